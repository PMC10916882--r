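# shared helpers: tiny configurations and cached fixtures built in code

# a physical configuration without driving, collisions or damping: the
# conservative core used by the energy and convergence checks
conservative_config <- function(...) {
  phys_config(p_s = 0, r_a = 0, xi_c = 0, ...)
}

# rest positions with a comfortably open glottis (no collisions at +-0.5 mm
# initial deflections)
open_rest <- function(gap_mm = 0.5) {
  rest_positions(c(-rep(gap_mm, 3), rep(gap_mm, 3)))
}

# deterministic micro-dataset shared across tests (built once per run)
.micro_env <- new.env(parent = emptyenv())
micro_dataset <- function(n = 64L, seed = 421L) {
  key <- sprintf("ds_%d_%d", n, seed)
  if (is.null(.micro_env[[key]])) {
    .micro_env[[key]] <- build_dataset(n, seed = seed)
  }
  .micro_env[[key]]
}

# small surrogate configuration: full architecture, reduced hidden size,
# so forward/backward tests stay fast
tiny_scfg <- function(...) {
  surrogate_config(gru_hidden = 8L, ...)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
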