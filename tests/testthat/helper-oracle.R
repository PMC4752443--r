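# Independent brute-force oracle for the hemiplasy null probability on
# the 4-taxon tree (((A,B):1,C):2,D):4 (node ages in coalescent units).
# Epoch-by-epoch direct simulation of the multispecies coalescent,
# Rao-Blackwellised over single-mutation placement: per genealogy, the
# fraction of total branch length whose derived carriers would be
# exactly {B,C} or exactly {A,D}.  Deliberately written as a separate
# algorithm from the package's structured-coalescent simulator.
oracle_q4 <- function(nrep, seed) {
  set.seed(seed)
  fracs <- numeric(nrep)
  for (r in seq_len(nrep)) {
    act_m <- list("A", "B")   # active lineages: member sets
    act_b <- c(0, 0)          # birth times (tips extend from 0)
    segs_m <- list(); segs_l <- numeric(0)
    t <- 1                     # A,B share an ancestor from 1 cu
    bounds <- c(2, 4, Inf)
    adds <- list("C", "D", NULL)
    for (ep in 1:3) {
      t_end <- bounds[ep]
      repeat {
        k <- length(act_m)
        if (k < 2) break
        dt <- stats::rexp(1, k * (k - 1) / 2)
        if (t + dt >= t_end) break
        t <- t + dt
        pick <- sample.int(k, 2)
        segs_m <- c(segs_m, act_m[pick])
        segs_l <- c(segs_l, t - act_b[pick])
        merged <- list(unlist(act_m[pick]))
        act_m <- c(act_m[-pick], merged)
        act_b <- c(act_b[-pick], t)
      }
      if (length(act_m) == 1 && ep == 3) break
      t <- max(t, t_end)
      if (!is.null(adds[[ep]])) {
        act_m <- c(act_m, list(adds[[ep]]))
        act_b <- c(act_b, 0)
      }
    }
    hit <- vapply(segs_m, function(m)
      setequal(m, c("B", "C")) || setequal(m, c("A", "D")), logical(1))
    fracs[r] <- sum(segs_l[hit]) / sum(segs_l)
  }
  list(q = mean(fracs), se = stats::sd(fracs) / sqrt(nrep))
}
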