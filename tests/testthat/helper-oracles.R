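# Independent oracles and fixture builders used across the suite.

random_textures <- function(nr, nc,
                            prob = c(cancer = .3, normal = .2, stroma = .2,
                                     blood = .1, empty = .1, other = .1)) {
  matrix(sample(names(prob), nr * nc, replace = TRUE, prob = prob), nr, nc)
}

random_map <- function(nr, nc, scores = FALSE, sample_id = "rnd", ...) {
  tx <- random_textures(nr, nc, ...)
  sc <- NULL
  if (scores) {
    sc <- matrix(runif(nr * nc), nr, nc)
    sc[tx == "empty"] <- NA_real_
  }
  tile_map(tx, sc, sample_id = sample_id)
}

# Seed derivation mirrored independently of the package internals.
oracle_seed <- function(seed, sample_id) {
  h <- 0
  for (k in utf8ToInt(as.character(sample_id))) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

# Majority vote with the tie hierarchy, written from the counts up.
oracle_vote <- function(labels) {
  cnt <- tabulate(factor(labels, levels = texture_labels()),
                  nbins = length(texture_labels()))
  names(cnt) <- texture_labels()
  tied <- names(cnt)[cnt == max(cnt) & cnt > 0]
  if ("cancer" %in% tied) return("cancer")
  if (length(tied) > 1 && "stroma" %in% tied) return("stroma")
  if (length(tied) == 1) return(tied)
  tied <- sort(tied)
  tied[sample.int(length(tied), 1)]
}

# Brute-force single pass: raster-order windows at stride offsets with the
# last offset clamped; counts from the pre-pooling grid; later window wins.
oracle_pool <- function(map, window = 3, stride = 2, seed = 0) {
  tx <- map$textures
  nr <- nrow(tx); nc <- ncol(tx)
  offs <- function(n) {
    o <- seq(1, n - window + 1, by = stride)
    if (o[length(o)] != n - window + 1) o <- c(o, n - window + 1)
    o
  }
  out <- tx
  withr::with_seed(oracle_seed(seed, map$sample_id), {
    for (r in offs(nr)) for (c in offs(nc)) {
      win <- as.vector(tx[r:(r + window - 1), c:(c + window - 1)])
      out[r:(r + window - 1), c:(c + window - 1)] <- oracle_vote(win)
    }
  })
  out
}

# Exhaustive per-tile minimum Chebyshev distance scan.
oracle_margin <- function(map, depth = 2) {
  tx <- map$textures
  nr <- nrow(tx); nc <- ncol(tx)
  can <- which(tx == "cancer", arr.ind = TRUE)
  reg <- matrix("non_margin", nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (tx[r, c] == "cancer") { reg[r, c] <- "core"; next }
    if (tx[r, c] == "empty") { reg[r, c] <- "background"; next }
    if (nrow(can)) {
      d <- min(pmax(abs(can[, 1] - r), abs(can[, 2] - c)))
      if (d <= depth) reg[r, c] <- "margin"
    }
  }
  reg
}

# Exhaustive-permutation two-sided Wilcoxon rank-sum (no ties expected).
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pool <- c(x, y)
  rk <- rank(pool)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(statistic = u_obs, p_value = p)
}

# Step-up Benjamini-Hochberg written directly from the formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

# Two-group log-rank chi-square from the O-E sums, no censoring assumed
# beyond what `event` encodes.
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tj in times) {
    at <- time >= tj
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(time == tj & event == 1)
    d1 <- sum(time == tj & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small biased two-centre cohort used by several harmonisation tests.
biased_cohort_config <- function(seed, samples_per_centre = 8) {
  synthetic_cohort_config(seed = seed, n_centres = 2,
                          samples_per_centre = samples_per_centre,
                          grid = c(32, 32),
                          p_nplus = c(0.95, 0.05),
                          core_frac = c(0.35, 0.5))
}
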