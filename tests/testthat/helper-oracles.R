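# Independent brute-force oracles used across the suite.

# One-way ANOVA by direct sum-of-squares arithmetic (no model fitting).
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(values, groups, function(v)
    (v - mean(v))^2)))
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(ss_between = ss_between, ss_within = ss_within,
       df1 = df1, df2 = df2, f = f,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Level pooling re-derived from first principles: greedy agglomeration with
# residual sums of squares computed by explicit arithmetic over every
# candidate pair of current blocks (ordered by |mean difference|), F test of
# the deviance increase against the current model at `alpha`.
oracle_pool <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  rss_of <- function(blocks) sum(unlist(lapply(blocks, function(b) {
    v <- values[groups %in% b]
    (v - mean(v))^2
  })))
  blocks <- as.list(levels(groups))
  repeat {
    if (length(blocks) == 1L) break
    rss_cur <- rss_of(blocks)
    df_cur <- length(values) - length(blocks)
    bm <- vapply(blocks, function(b) mean(values[groups %in% b]), 0)
    cand <- list(); dmean <- numeric()
    for (i in seq_len(length(blocks) - 1)) for (j in (i + 1):length(blocks)) {
      cand[[length(cand) + 1L]] <- c(i, j)
      dmean <- c(dmean, abs(bm[i] - bm[j]))
    }
    merged <- FALSE
    for (k in order(dmean)) {
      ij <- cand[[k]]
      nb <- blocks
      nb[[ij[1]]] <- c(nb[[ij[1]]], nb[[ij[2]]])
      nb[[ij[2]]] <- NULL
      d_dev <- rss_of(nb) - rss_cur
      p <- if (rss_cur <= 1e-12 * (mean(values^2) + 1)) {
        if (d_dev <= 1e-12) 1 else 0
      } else pf(d_dev / (rss_cur / df_cur), 1, df_cur, lower.tail = FALSE)
      if (p > alpha) { blocks <- nb; merged <- TRUE; break }
    }
    if (!merged) break
  }
  canonical_partition(blocks)
}

# Order-independent canonical form of a partition (list of level vectors).
canonical_partition <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, `[`, "", 1))]
}

# Small valid two-population dataset used by several structural tests.
tiny_dataset <- function() {
  measurement_dataset(data.frame(
    population_id = rep(c("P1", "P2"), each = 4),
    specimen_id = rep(c("a", "b"), each = 4),
    long_arm_um = c(3.0, 2.6, 2.2, 1.9, 2.9, 2.5, 2.1, 1.8),
    short_arm_um = c(2.8, 2.5, 2.0, 1.8, 2.7, 2.4, 2.0, 1.7)))
}
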