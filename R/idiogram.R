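#' Build an idiogram from a population summary
#'
#' One entry per homologue pair in rank order: the pair's relative length
#' as a percentage of the haploid karyotype length (pair means sum to
#' 100), the centromere position as the short-arm fraction
#' S/(L+S) = 1/(1+r) computed from the pair's mean arm ratio, and the
#' morphology class.
#'
#' @param summary a `population_summary` from [summarize_population()].
#' @return object of class `idiogram`: data.frame with columns `pair`,
#'   `relative_length_pct`, `centromere_position_fraction`, `morphology`;
#'   attribute `population_id`.
#' @export
build_idiogram <- function(summary) {
  stopifnot(inherits(summary, "population_summary"))
  if (is.null(summary$mean_r) || any(!is.finite(summary$mean_r)))
    stop_domain("summary lacks arm (mean_r) data")
  pair_tl <- tapply(summary$mean_tl_um, summary$pair, mean)
  pair_r <- tapply(summary$mean_r, summary$pair, mean)
  pairs <- as.integer(names(pair_tl))
  ord <- order(pairs)
  pair_tl <- as.numeric(pair_tl)[ord]; pair_r <- as.numeric(pair_r)[ord]
  pairs <- pairs[ord]
  haploid_kl <- sum(pair_tl)
  out <- data.frame(
    pair = pairs,
    relative_length_pct = pair_tl * 100 / haploid_kl,
    centromere_position_fraction = 1 / (1 + pair_r),
    morphology = classify_morphology(pair_r),
    stringsAsFactors = FALSE)
  structure(out, population_id = attr(summary, "population_id"),
            haploid_kl_um = haploid_kl,
            class = c("idiogram", "data.frame"))
}

#' Render an idiogram to SVG
#'
#' Writes a deterministic standalone SVG: one vertical bar per homologue
#' pair, height proportional to relative length, with the centromere drawn
#' as a constriction at the short-arm fraction measured from the top
#' (short arm up, the usual idiogram orientation).  The output is a pure
#' function of the idiogram and style, so repeated renders are
#' byte-identical.
#'
#' @param idiogram an [build_idiogram()] result.
#' @param path output `.svg` path.
#' @param style named list of overrides: `bar_width`, `gap`, `height`,
#'   `fill`, `stroke`.
#' @return `path`, invisibly.
#' @export
render_idiogram <- function(idiogram, path, style = list()) {
  stopifnot(inherits(idiogram, "idiogram"))
  st <- utils::modifyList(list(bar_width = 24, gap = 14, height = 220,
                               fill = "#9ecae1", stroke = "#333333"),
                          style)
  n <- nrow(idiogram)
  margin <- 30
  width <- margin * 2 + n * st$bar_width + (n - 1) * st$gap
  total_h <- margin * 2 + st$height + 20
  max_rl <- max(idiogram$relative_length_pct)
  fmt <- function(x) formatC(x, format = "f", digits = 2)

  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, total_h, width, total_h),
    sprintf('<title>Idiogram %s</title>', attr(idiogram, "population_id")))
  for (i in seq_len(n)) {
    x <- margin + (i - 1) * (st$bar_width + st$gap)
    h <- st$height * idiogram$relative_length_pct[i] / max_rl
    y <- margin + st$height - h
    cen_y <- y + h * idiogram$centromere_position_fraction[i]
    lines <- c(lines,
      sprintf(paste0('<rect x="%s" y="%s" width="%s" height="%s" rx="6" ',
                     'fill="%s" stroke="%s"/>'),
              fmt(x), fmt(y), fmt(st$bar_width), fmt(h),
              st$fill, st$stroke),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2"/>',
              fmt(x - 2), fmt(cen_y), fmt(x + st$bar_width + 2), fmt(cen_y),
              st$stroke),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%d</text>',
              fmt(x + st$bar_width / 2), fmt(margin + st$height + 14),
              idiogram$pair[i]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full karyomorphometric pipeline
#'
#' Executes summary -> morphometry -> population statistics ->
#' (optionally) flow cytometry -> idiograms from a single configuration,
#' and writes a CSV/JSON/SVG report bundle.
#'
#' The configuration (a YAML file path or an equivalent named list) has
#' keys:
#' \describe{
#'   \item{input}{either `measurements:` (path to a measurement CSV/TSV)
#'     or `simulate: {seed: <int>}` to generate data from the packaged
#'     population parameters; exactly one is required.}
#'   \item{flow}{optional; `histograms:` a named list (population ->
#'     histogram CSV path) and optional `standard_1c_pg`.}
#'   \item{output}{`dir:` output directory (created).}
#'   \item{alpha}{significance level for contrasts (default 0.05).}
#'   \item{stamp}{logical; include a timestamp in the report (default
#'     `FALSE`, so identical inputs give byte-identical bundles).}
#' }
#'
#' @param config path to a YAML file or a named list.
#' @return invisibly, a list with the population summaries, the karyotype
#'   report, statistics tables, and output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_domain("config must be a list or YAML path")
  if (is.null(config$output) || is.null(config$output$dir))
    stop_domain("config missing required key: output.dir")
  if (is.null(config$input))
    stop_domain("config missing required key: input")
  alpha <- config$alpha %||% 0.05
  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dataset <- if (!is.null(config$input$measurements)) {
    read_measurements(config$input$measurements)
  } else if (!is.null(config$input$simulate)) {
    seed <- config$input$simulate$seed %||%
      stop_domain("config missing key: input.simulate.seed")
    simulate_study(table1_params(), seed = seed)
  } else stop_domain("config input needs either `measurements` or `simulate`")

  pops <- sort(unique(dataset$population_id))
  summaries <- lapply(pops, function(p) summarize_population(dataset, p))
  names(summaries) <- pops

  per_pop <- lapply(pops, function(p) {
    s <- summaries[[p]]
    meta <- split(as.data.frame(dataset)[dataset$population_id == p, ],
                  dataset$specimen_id[dataset$population_id == p])
    kls <- vapply(meta, karyotype_length, 0)
    ais <- vapply(meta, asymmetry_index, 0)
    kf <- karyotype_formula(s$morphology)
    list(population_id = p,
         n_metaphases = attr(s, "n_metaphases"),
         karyotype_length_um = attr(s, "karyotype_length_um"),
         karyotype_formula = kf$formula_string,
         arm_number_2AN = kf$arm_number_2AN,
         ploidy_2n = kf$ploidy_2n,
         mean_asymmetry_index_pct = mean(ais),
         kl_cv = if (length(kls) >= 2) karyotype_cv(kls) else NA_real_)
  })
  names(per_pop) <- pops

  # population comparison on per-metaphase KL
  meta_all <- split(as.data.frame(dataset),
                    list(dataset$population_id, dataset$specimen_id),
                    drop = TRUE)
  kl_vals <- vapply(meta_all, karyotype_length, 0)
  kl_pops <- vapply(meta_all, function(m) m$population_id[1], "")
  stats_out <- NULL
  if (length(unique(kl_pops)) >= 2 && any(table(kl_pops) >= 2)) {
    kl_test <- anodev_oneway(kl_vals, kl_pops)
    kl_group <- pool_levels(kl_vals, kl_pops, alpha = alpha)
    per_chr <- if (min(table(kl_pops)) >= 2)
      per_chromosome_tests(dataset, alpha = alpha) else NULL
    stats_out <- list(kl_anodev = kl_test, kl_grouping = kl_group,
                      per_chromosome = per_chr)
  }

  # write bundle
  paths <- list()
  for (p in pops) {
    f <- file.path(out_dir, paste0("summary_", p, ".csv"))
    write.csv(as.data.frame(summaries[[p]]), f, row.names = FALSE,
              quote = FALSE)
    paths[[paste0("summary_", p)]] <- f
    idg <- build_idiogram(summaries[[p]])
    f2 <- file.path(out_dir, paste0("idiogram_", p, ".svg"))
    render_idiogram(idg, f2)
    paths[[paste0("idiogram_", p)]] <- f2
  }
  if (!is.null(stats_out)) {
    if (!is.null(stats_out$per_chromosome)) {
      f <- file.path(out_dir, "per_chromosome_tests.csv")
      write.csv(stats_out$per_chromosome, f, row.names = FALSE, quote = FALSE)
      paths$per_chromosome <- f
    }
  }

  report <- list(
    populations = lapply(per_pop, function(p)
      p[c("population_id", "n_metaphases", "karyotype_length_um",
          "karyotype_formula", "arm_number_2AN", "ploidy_2n",
          "mean_asymmetry_index_pct", "kl_cv")]),
    kl_comparison = if (!is.null(stats_out)) list(
      deviance = stats_out$kl_anodev$deviance_explained,
      df = c(stats_out$kl_anodev$df_factor,
             stats_out$kl_anodev$df_residual),
      p_value = stats_out$kl_anodev$p_value,
      letters = as.list(stats_out$kl_grouping$letters)) else NULL)
  if (isTRUE(config$stamp))
    report$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$report <- f

  invisible(list(dataset = dataset, summaries = summaries,
                 populations = per_pop, stats = stats_out, paths = paths))
}
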