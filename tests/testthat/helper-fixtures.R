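# shared fixtures built in code

tiny_config <- function(n = 30, seed = 101, ...) {
  cohort_config(n_participants = n, master_seed = seed, ...)
}

# brute-force Mann-Whitney U for sample a vs b: pairs where a_i > b_j count 1,
# ties count 1/2 (rank-sum convention); returns min(U1, U2)
brute_force_U <- function(a, b) {
  U1 <- sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  min(U1, length(a) * length(b) - U1)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enumerate_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  obs <- brute_force_U(a, b)
  us <- apply(idx, 2, function(ii) brute_force_U(pooled[ii], pooled[-ii]))
  mean(us <= obs)
}

# random valid ratings block
random_block <- function(n_pic, k, max = 100) {
  matrix(runif(n_pic * k, 0, max), n_pic, k)
}
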