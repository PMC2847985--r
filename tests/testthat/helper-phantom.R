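# Shared fixtures: the default-geometry template is expensive enough to build
# once per run; lesions and masks derive from it in the tests.

.fixture_env <- new.env(parent = emptyenv())

default_template <- function() {
  tpl <- get0("template", envir = .fixture_env, inherits = FALSE)
  if (is.null(tpl)) {
    tpl <- build_template(acq_geometry())
    assign("template", tpl, envir = .fixture_env)
  }
  tpl
}

tpl_mask <- function(what) template_mask(default_template(), what)

# Independent brute-force oracle for the exact Wilcoxon signed-rank test:
# enumerate all 2^n sign assignments of the observed ranks explicitly.
wilcoxon_enumeration_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  p_le <- mean(Ws <= W)
  p_ge <- mean(Ws >= W)
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# Independent brute-force oracle for the T2 fit: dense grid search over T2
# with the profiled least-squares S0 (optimal S0 given T2 is linear).
t2_grid_search_oracle <- function(y, te, t2_grid = seq(5, 150, by = 0.01)) {
  E <- exp(-outer(t2_grid, te, function(t2, te) te / t2))
  s0_hat <- (E %*% y) / rowSums(E * E)
  sse <- rowSums((matrix(y, nrow = length(t2_grid), ncol = length(te),
                         byrow = TRUE) - as.numeric(s0_hat) * E)^2)
  t2_grid[which.min(sse)]
}

# single-voxel echo train as a 1x1x1 4-D array
voxel_echo_train <- function(s0, t2, te) {
  array(s0 * exp(-te / t2), dim = c(1, 1, 1, length(te)))
}
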