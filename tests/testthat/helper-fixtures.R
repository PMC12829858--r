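# Shared fixture builders; everything is generated in code at test time.

# minimal wide sample table
tiny_table <- function(values, group, species = "human",
                       analytes = paste0("C", 14 + seq_len(ncol(values)), ":0")) {
  values <- as.matrix(values)
  df <- data.frame(sample_id = sprintf("s%02d", seq_len(nrow(values))),
                   species = species, group = group,
                   stringsAsFactors = FALSE)
  colnames(values) <- analytes
  as_sample_table(cbind(df, as.data.frame(values)))
}

# small simulation config on a reduced panel
small_config <- function(k = 3, n_control = 10, n_case = 10, fold = 1,
                         log_sd = 0.5, seed = 1L) {
  panel <- ffa_panel()[seq_len(k), ]
  panel$log_sd <- log_sd
  panel$case_fold_change <- rep_len(fold, k)
  sim_config(panel, n_control, n_case, seed = seed)
}

# exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(m + n, m) group assignments of the pooled ranks
mw_exact_enum <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2L, function(i) sum(r[i]) - m * (m + 1) / 2)
  pl <- mean(us <= u_obs); pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Cartesian shoelace area of the polygon with radii r on equiangular axes
shoelace_area <- function(r) {
  k <- length(r)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  x <- r * cos(ang); y <- r * sin(ang)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# tie-corrected Kruskal-Wallis H from the defining formula
kw_formula <- function(groups) {
  v <- unlist(groups); N <- length(v)
  r <- rank(v)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) length(ri) * mean(ri)^2, 0)) -
    3 * (N + 1)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
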