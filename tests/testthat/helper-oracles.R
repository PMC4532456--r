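# Independent slow-path oracle: evaluates the system map state by state
# through the scalar function API (nor_fn, threshold_fn, ...) and plain
# loops, never touching the vectorized engine or the phase-space
# derivation code.

slow_map <- function(sys, state) {
  state <- as.integer(state)
  for (block in sys$scheme$blocks) {
    src <- state
    for (v in block) {
      vf <- sys$functions[[v]]
      nbr <- sys$graph$nbr[[v]]
      inputs <- src[nbr]
      state[v] <- switch(vf$family,
        nor = nor_fn(inputs),
        threshold = threshold_fn(inputs, vf$k),
        bithreshold = bithreshold_fn(src[v], inputs, vf$k01, vf$k10),
        multithreshold = multithreshold_fn(src[v], sum(inputs), vf$k, r = vf$r),
        linear_threshold = linear_threshold_fn(inputs, sys$graph$wts[[v]], vf$k),
        truth_table = vf$outputs[encode_state(inputs, vf$r) + 1L],
        stop("no slow path for family ", vf$family))
    }
  }
  state
}

# Brute-force attractor membership: iterate the slow map r^n times (must
# land on the cycle), then walk the cycle to measure its period.
slow_orbit <- function(sys, state) {
  N <- sys$r^sys$n
  x <- state
  steps_to_cycle <- NA_integer_
  for (i in seq_len(N)) x <- slow_map(sys, x)   # now certainly periodic
  anchor <- x
  period <- 0L
  repeat {
    x <- slow_map(sys, x)
    period <- period + 1L
    if (identical(x, anchor)) break
  }
  # transient: first time the trajectory hits a state of the cycle
  cyc <- vector("list", period)
  cyc[[1]] <- anchor
  if (period > 1) for (i in 2:period) cyc[[i]] <- slow_map(sys, cyc[[i - 1]])
  keys <- vapply(cyc, paste, character(1), collapse = ",")
  x <- state
  transient <- 0L
  while (!paste(x, collapse = ",") %in% keys) {
    x <- slow_map(sys, x)
    transient <- transient + 1L
  }
  list(period = period, transient = transient,
       cycle_min = min(vapply(cyc, encode_state, numeric(1), r = sys$r)))
}

circle4_nor <- function(scheme) {
  gds(make_template("circle", n = 4, self_loops = TRUE), vf_nor(), scheme)
}
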