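# Shared fixture builders (everything is generated in code; no stored data).

# small camera for fast frame-level tests
test_camera <- function(n = 64, gain = 0.5, offset = 100)
  camera_model(width = n, height = n, gain = gain, offset = offset)

# expected-photon model of a single 9x9 ROI at the given parameters
roi_model <- function(x, y, I, bg, sigma = 1.0, n = 9)
  matrix(seqsmlm:::cpp_roi_mu(matrix(c(x, y, I, bg), nrow = 1), sigma,
                              as.integer(n)), n, n)

# Poisson draws of a ROI model as a pixels x N matrix
roi_draws <- function(mu, N) matrix(rpois(length(mu) * N, as.numeric(mu)),
                                    length(mu), N)

# minimal localization table from bare coordinates
loc_table <- function(x, y, sx = 10, sy = 10) {
  n <- length(x)
  data.frame(frame = seq_len(n), x_nm = x, y_nm = y,
             x_px = x / 106.7, y_px = y / 106.7,
             photons = rep(1000, n), bg = rep(5, n),
             sigma_x_nm = rep(sx, length.out = n),
             sigma_y_nm = rep(sy, length.out = n),
             pvalue = rep(0.5, n), converged = rep(TRUE, n),
             accepted = rep(TRUE, n))
}

# default-texture volume shared by registration tests (expensive to build)
shared_volume <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- brightfield_volume(seed = 5)
    cache
  }
})
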