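# fixtures shared across test files; everything is built in code

toggle_fixture <- function(gradient = gradient_static(b = 2, lam = 0.35)) {
  default_toggle(gradient)
}

scalar_fixture <- function(D = 0.1, alpha = 0.1, L = 1) {
  build_model("scalar", scalar_params(D, alpha), L = L)
}

# symmetric two-input toggle with antiparallel tabulated gradients
toggle2_fixture <- function(D1 = 1, D2 = 1, L = 100, lam = 40, b = 4) {
  p <- toggle_params(a1 = 1.7, a2 = 1.7, beta = 0.35,
                     act = hill_params(0.75, 2), rep = hill_params(1, 2),
                     D1 = D1, D2 = D2)
  xs <- seq(0, L, length.out = 201L)
  g1 <- gradient_static(b, lam)
  g2 <- gradient_tabulated(data.frame(x = xs, value = b * exp(-(L - xs) / lam)))
  build_model("toggle2", p, list(g1, g2), L = L)
}

# a zero-reaction diffusing model, for conservation checks
diffusion_only_model <- function(D = 0.5, L = 1) {
  m <- build_model("scalar", scalar_params(D, 0.5), L = L)
  m$rhs_vec <- function(t, xs, U) U * 0
  m$rhs <- function(t, x, u) u * 0
  m$jac <- function(t, x, u) matrix(0, 1L, 1L)
  m$local_reaction <- NULL
  m
}

expect_no_mixing_R0 <- function(res) {
  testthat::expect_equal(res$R, 0)
  testthat::expect_equal(res$x_tilde_a, res$x_tilde_p)
}
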