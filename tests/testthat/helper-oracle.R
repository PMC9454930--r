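# Independent brute-force oracle for the Markov engine.
#
# Builds one-cycle matrices directly from the documented event ordering
# (background death, then diagnosis among survivors, then false positive
# among surviving undiagnosed) without calling transition_probs(), and
# computes state occupancy after k cycles by explicit enumeration of all
# 5^k state paths. Used to cross-check the engine on short horizons.

oracle_states <- c("healthy", "localized", "disseminated", "false_positive",
                   "dead")

oracle_matrix <- function(q, rate, od, frac_loc, fp, hr_loc, hr_diss) {
  plc <- min(1, (1 - exp(-rate)) * od)
  surv <- 1 - q
  m <- matrix(0, 5, 5, dimnames = list(oracle_states, oracle_states))
  m[1, ] <- c(surv * (1 - plc) * (1 - fp), surv * plc * frac_loc,
              surv * plc * (1 - frac_loc), surv * (1 - plc) * fp, q)
  pL <- 1 - (1 - q)^hr_loc
  pD <- 1 - (1 - q)^hr_diss
  m[2, ] <- c(0, 1 - pL, 0, 0, pL)
  m[3, ] <- c(0, 0, 1 - pD, 0, pD)
  m[4, ] <- c(1 - q, 0, 0, 0, q)
  m[5, 5] <- 1
  m
}

# occupancy after k transitions starting from healthy, by path enumeration;
# mats is a list of k one-cycle matrices (cycle 0 first)
oracle_occupancy <- function(mats) {
  k <- length(mats)
  paths <- expand.grid(rep(list(1:5), k))
  occ <- numeric(5)
  for (i in seq_len(nrow(paths))) {
    s <- 1
    pr <- 1
    for (t in seq_len(k)) {
      s2 <- paths[i, t]
      pr <- pr * mats[[t]][s, s2]
      s <- s2
    }
    occ[s] <- occ[s] + pr
  }
  stats::setNames(occ, oracle_states)
}
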