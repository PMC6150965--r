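#' One-way Gaussian analysis of deviance
#'
#' Fits a Gaussian identity-link GLM of the measurements on the group
#' factor and tests the group effect by the F ratio of the explained
#' deviance against the residual deviance.  For a Gaussian model the
#' deviance is the residual sum of squares, so this is exactly a one-way
#' ANOVA: `deviance_explained` is the between-group sum of squares,
#' `F = (deviance/df_factor) / (residual/df_residual)`.
#'
#' Degenerate data are reported rather than erroring: zero between-group
#' deviance gives p = 1; zero residual deviance with a non-zero group
#' effect gives p = 0 with `degenerate = TRUE`.
#'
#' @param values numeric measurements.
#' @param groups parallel vector of level labels (>= 2 distinct levels).
#' @return object of class `anodev`: list with `deviance_explained`,
#'   `df_factor`, `df_residual`, `statistic` (F), `p_value`, `degenerate`,
#'   `group_means`.
#' @examples
#' anodev_oneway(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
#' @export
anodev_oneway <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_domain("need >= 2 group levels")
  if (length(values) != length(groups))
    stop_domain("values and groups must have equal length")
  if (any(!is.finite(values))) stop_domain("values must be finite")

  fit <- glm(values ~ groups, family = gaussian())
  null_fit <- glm(values ~ 1, family = gaussian())
  dev_expl <- null_fit$deviance - fit$deviance
  df_factor <- nlevels(groups) - 1L
  df_residual <- fit$df.residual
  scale <- mean(values^2) + 1
  eps <- 1e-12 * scale

  degenerate <- FALSE
  if (dev_expl <= eps) {
    stat <- 0; p <- 1
  } else if (fit$deviance <= eps || df_residual == 0L) {
    stat <- Inf; p <- 0; degenerate <- TRUE
  } else {
    stat <- (dev_expl / df_factor) / (fit$deviance / df_residual)
    p <- pf(stat, df_factor, df_residual, lower.tail = FALSE)
  }
  structure(list(deviance_explained = max(dev_expl, 0),
                 df_factor = df_factor, df_residual = as.integer(df_residual),
                 statistic = stat, p_value = p, degenerate = degenerate,
                 group_means = tapply(values, groups, mean)),
            class = "anodev")
}

#' @export
print.anodev <- function(x, ...) {
  cat(sprintf("Analysis of deviance: Deviance(%d,%d) = %.4g, F = %.4g, p = %.4g%s\n",
              x$df_factor, x$df_residual, x$deviance_explained, x$statistic,
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Residual sum of squares of a grouping where each block of levels shares
# one mean. `blocks` is a list of character vectors of level names.
block_rss <- function(values, groups, blocks) {
  if (length(blocks) == 1L)
    return(glm(values ~ 1, family = gaussian())$deviance)
  merged <- merged_factor(groups, blocks)
  glm(values ~ merged, family = gaussian())$deviance
}

merged_factor <- function(groups, blocks) {
  map <- setNames(rep(seq_along(blocks), lengths(blocks)),
                  unlist(blocks))
  factor(map[as.character(groups)])
}

#' Pool statistically indistinguishable factor levels
#'
#' Iterative contrast analysis by level aggregation: starting from one
#' block per level, repeatedly consider merging pairs of current blocks in
#' ascending order of the absolute difference of their block means; a merge
#' is accepted when the increase in residual deviance it causes is not
#' significant by an F test at `alpha` against the current (unmerged)
#' model, i.e. when the pooled model does not fit significantly worse.
#' After each accepted merge the block structure is recomputed; pooling
#' stops when no candidate merge is acceptable.  Blocks receive compact
#' letters in order of descending block mean ("a" = largest); levels share
#' a letter iff they were pooled into the same block.
#'
#' @inheritParams anodev_oneway
#' @param alpha significance level for the merge test (default 0.05).
#' @return object of class `grouping_result`: list with `partition` (list
#'   of character vectors of level names), `letters` (named character,
#'   level -> letter), `block_means`, `alpha`, `degenerate`.
#' @examples
#' set.seed(1)
#' g <- rep(c("x", "y", "z"), each = 10)
#' v <- rnorm(30, mean = c(0, 0, 100)[match(g, c("x", "y", "z"))])
#' pool_levels(v, g)$letters
#' @export
pool_levels <- function(values, groups, alpha = 0.05) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_domain("need >= 2 group levels")
  lvls <- levels(groups)
  scale <- mean(values^2) + 1
  eps <- 1e-12 * scale

  total_var <- sum((values - mean(values))^2)
  if (total_var <= eps) {
    blocks <- list(lvls)
    return(new_grouping(blocks, values, groups, alpha, degenerate = TRUE))
  }

  blocks <- as.list(lvls)
  repeat {
    if (length(blocks) == 1L) break
    rss_cur <- block_rss(values, groups, blocks)
    df_cur <- length(values) - length(blocks)
    bm <- vapply(blocks, function(b)
      mean(values[groups %in% b]), 0)
    pairs <- utils::combn(length(blocks), 2)
    dmean <- abs(bm[pairs[1, ]] - bm[pairs[2, ]])
    ord <- order(dmean)
    merged_any <- FALSE
    for (k in ord) {
      i <- pairs[1, k]; j <- pairs[2, k]
      cand <- blocks
      cand[[i]] <- c(cand[[i]], cand[[j]])
      cand[[j]] <- NULL
      rss_new <- block_rss(values, groups, cand)
      d_dev <- max(rss_new - rss_cur, 0)
      # pooled model loses 1 df; test against the current model's scale
      if (df_cur <= 0L || rss_cur <= eps) {
        p_merge <- if (d_dev <= eps) 1 else 0
      } else {
        f <- (d_dev / 1) / (rss_cur / df_cur)
        p_merge <- pf(f, 1, df_cur, lower.tail = FALSE)
      }
      if (p_merge > alpha) {
        blocks <- cand
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  new_grouping(blocks, values, groups, alpha, degenerate = FALSE)
}

new_grouping <- function(blocks, values, groups, alpha, degenerate) {
  bm <- vapply(blocks, function(b) mean(values[groups %in% b]), 0)
  ord <- order(-bm)
  blocks <- blocks[ord]; bm <- bm[ord]
  blocks <- lapply(blocks, sort)
  letts <- letters[seq_along(blocks)]
  lmap <- setNames(rep(letts, lengths(blocks)), unlist(blocks))
  lmap <- lmap[levels(groups)]
  structure(list(partition = blocks,
                 letters = lmap,
                 block_means = setNames(bm, letts),
                 alpha = alpha, degenerate = degenerate),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("Level pooling (alpha =", x$alpha, "):\n")
  for (i in seq_along(x$partition))
    cat(sprintf("  %s: {%s}  mean = %.4g\n", names(x$block_means)[i],
                paste(x$partition[[i]], collapse = ", "),
                x$block_means[i]))
  invisible(x)
}

#' Per-chromosome analysis of deviance across populations
#'
#' Tests, for every homologue pair rank, whether chromosome total length
#' differs among populations, using both homologues of each metaphase as
#' observations (so 5 populations x 10 metaphases give df (4, 95)); runs
#' the level-pooling contrast analysis per rank.  P-values are reported raw
#' by default; Holm correction across the ranks is available.
#'
#' @param dataset a [measurement_dataset()] covering >= 2 populations, all
#'   sharing 2n.
#' @param alpha significance level for pooling.
#' @param correction `"none"` (default) or any method of
#'   [stats::p.adjust()].
#' @return data.frame with one row per pair (`pair`, `deviance`,
#'   `df_factor`, `df_residual`, `statistic`, `p_value`, `p_adjusted`, and
#'   one `letter_<population>` column per population); attribute
#'   `groupings` holds the full [pool_levels()] result per pair.
#' @export
per_chromosome_tests <- function(dataset, alpha = 0.05,
                                 correction = "none") {
  x <- as.data.frame(dataset)
  if (length(unique(x$population_id)) < 2)
    stop_domain("need >= 2 populations")
  x$pair <- homologue_pair(x$chromosome_index)
  pairs <- sort(unique(x$pair))
  pops <- sort(unique(x$population_id))

  tests <- lapply(pairs, function(p) {
    sub <- x[x$pair == p, ]
    a <- anodev_oneway(sub$total_length_um, sub$population_id)
    g <- pool_levels(sub$total_length_um, sub$population_id, alpha = alpha)
    list(anodev = a, grouping = g)
  })
  p_raw <- vapply(tests, function(t) t$anodev$p_value, 0)
  p_adj <- stats::p.adjust(p_raw, method = correction)

  out <- data.frame(
    pair = pairs,
    deviance = vapply(tests, function(t) t$anodev$deviance_explained, 0),
    df_factor = vapply(tests, function(t) t$anodev$df_factor, 0L),
    df_residual = vapply(tests, function(t) t$anodev$df_residual, 0L),
    statistic = vapply(tests, function(t) t$anodev$statistic, 0),
    p_value = p_raw, p_adjusted = p_adj)
  for (pop in pops)
    out[[paste0("letter_", pop)]] <-
      vapply(tests, function(t) unname(t$grouping$letters[pop]), "")
  attr(out, "groupings") <- lapply(tests, `[[`, "grouping")
  out
}
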