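# End-to-end orchestration of one native-vs-invasive niche comparison and
# report rendering (tables, density figures, correlation circle).

#' Assemble an analysis configuration
#'
#' @param species species label.
#' @param occurrences named list of `occurrence_set` (one per range), or the
#'   path of an occurrence CSV (columns species,range,lon,lat).
#' @param climate a `climate_stack`, or a character vector of raster paths.
#' @param native_range label of the native range; all other ranges are treated
#'   as invasive.
#' @param variable_mode `"all"`, `"selected"`, or both.
#' @param thinning_km spatial thinning distance (km).
#' @param buffer_deg background dispersion buffer (degrees).
#' @param R niche grid resolution (cells per axis).
#' @param bandwidth kernel bandwidth rule/value (see [build_niche_grid()]).
#' @param q occupied-mask trim quantile for the dynamics indices.
#' @param intersection_mode scope for the dynamics indices
#'   (see [dynamics_indices()]).
#' @param n_reps randomizations for the equivalency/similarity tests.
#' @param alpha significance level used to star similarity p-values.
#' @param seed integer seed driving every stochastic stage.
#' @param directions which similarity-test directions to run
#'   (`"1->2"` = native vs invasive, `"2->1"` = invasive vs native).
#' @param betas,corr_threshold,contrib_threshold variable-selection controls
#'   (see [select_variables()]).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(species, occurrences, climate, native_range,
                            variable_mode = c("all", "selected"),
                            thinning_km = 5, buffer_deg = 1, R = 100,
                            bandwidth = "reference", q = 0.1,
                            intersection_mode = "analogue-only",
                            n_reps = 100, alpha = 0.05, seed = 1L,
                            directions = c("1->2", "2->1"),
                            betas = 1:6, corr_threshold = 0.7,
                            contrib_threshold = 0.05) {
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  ranges <- vapply(occurrences, function(o) o$range_label, character(1))
  names(occurrences) <- ranges
  if (!native_range %in% ranges)
    stop("native_range '", native_range, "' not among the ranges: ",
         paste(ranges, collapse = ", "), call. = FALSE)
  if (length(ranges) < 2)
    stop("need at least 2 ranges (one native, one invasive)", call. = FALSE)
  if (is.character(climate)) climate <- read_stack(climate)
  variable_mode <- match.arg(variable_mode, several.ok = TRUE)
  directions <- match.arg(directions, c("1->2", "2->1"), several.ok = TRUE)
  structure(
    list(species = species, occurrences = occurrences, climate = climate,
         native_range = native_range, variable_mode = variable_mode,
         thinning_km = thinning_km, buffer_deg = buffer_deg, R = R,
         bandwidth = bandwidth, q = q, intersection_mode = intersection_mode,
         n_reps = n_reps, alpha = alpha, seed = as.integer(seed),
         directions = directions, betas = betas,
         corr_threshold = corr_threshold,
         contrib_threshold = contrib_threshold),
    class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML file carries scalar fields of [analysis_config()] plus
#' `occurrence_csv` and `climate_paths` (relative paths are resolved against
#' the YAML file's directory).
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  args <- obj[setdiff(names(obj), c("occurrence_csv", "climate_paths"))]
  args$occurrences <- resolve(obj$occurrence_csv)
  args$climate <- resolve(unlist(obj$climate_paths))
  do.call(analysis_config, args)
}

#' Run one native-vs-invasive niche comparison
#'
#' Executes the full pipeline for one range pair: spatial thinning, buffered
#' minimum-convex-polygon backgrounds, background climate sampling, optional
#' AICc variable selection, pooled-background PCA, kernel-smoothed corrected
#' occupancy grids, Schoener's D, equivalency and similarity tests (both
#' directions), and the expansion/stability/unfilling indices. Deterministic
#' for a fixed config seed.
#'
#' @param config an `analysis_config`.
#' @param invasive_range label of the invasive range to compare against the
#'   native range.
#' @return an object of class `niche_comparison`: `report` (one data.frame row
#'   per variable mode x direction) plus the fitted objects (`pca`, `grids`,
#'   `selection`, `tests`, `dynamics`, keyed by variable mode).
#' @export
run_comparison <- function(config, invasive_range) {
  stopifnot(inherits(config, "analysis_config"))
  if (!invasive_range %in% names(config$occurrences))
    stop("unknown invasive range '", invasive_range, "'", call. = FALSE)
  if (identical(invasive_range, config$native_range))
    stop("invasive range must differ from the native range", call. = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed for pair ", config$native_range,
           " vs ", invasive_range, ": ", conditionMessage(e), call. = FALSE))
  }

  occ_n <- stage("thinning", thin_occurrences(
    config$occurrences[[config$native_range]], config$thinning_km,
    seed = child_seed(config$seed, "thin-native")))
  occ_i <- stage("thinning", thin_occurrences(
    config$occurrences[[invasive_range]], config$thinning_km,
    seed = child_seed(config$seed, "thin-invasive")))
  bg_n <- stage("background", build_background(occ_n, config$buffer_deg))
  bg_i <- stage("background", build_background(occ_i, config$buffer_deg))
  env_bg_n <- stage("background-climate",
                    background_sites(bg_n, config$climate))
  env_bg_i <- stage("background-climate",
                    background_sites(bg_i, config$climate))
  env_occ_n <- stage("extraction", extract_env(config$climate, occ_n$points))
  env_occ_i <- stage("extraction", extract_env(config$climate, occ_i$points))

  modes <- list()
  rows <- list()
  for (mode in config$variable_mode) {
    selection <- NULL
    vars <- stack_vars(config$climate)
    if (mode == "selected") {
      selection <- stage("variable-selection", select_variables(
        rbind(env_occ_n, env_occ_i), rbind(env_bg_n, env_bg_i),
        betas = config$betas, corr_threshold = config$corr_threshold,
        contrib_threshold = config$contrib_threshold,
        seed = child_seed(config$seed, "varsel")))
      vars <- selection$selected_variables
    }
    pca <- stage("pca", fit_pca(rbind(env_bg_n, env_bg_i)[, vars,
                                                          drop = FALSE]))
    sc_occ_n <- project_scores(pca, env_occ_n)
    sc_occ_i <- project_scores(pca, env_occ_i)
    sc_bg_n <- project_scores(pca, env_bg_n)
    sc_bg_i <- project_scores(pca, env_bg_i)
    extent <- score_extent(sc_occ_n, sc_occ_i, sc_bg_n, sc_bg_i)
    g_n <- stage("niche-grid", build_niche_grid(
      sc_occ_n, sc_bg_n, extent, config$R, config$bandwidth))
    g_i <- stage("niche-grid", build_niche_grid(
      sc_occ_i, sc_bg_i, extent, config$R, config$bandwidth))
    d_obs <- schoener_d(g_n, g_i)
    equiv <- stage("equivalency-test", equivalency_test(
      sc_occ_n, sc_occ_i, sc_bg_n, sc_bg_i, extent = extent, R = config$R,
      bandwidth = config$bandwidth, n_reps = config$n_reps,
      seed = child_seed(config$seed, paste0("equiv-", mode))))
    sims <- list()
    for (dir in config$directions) {
      sims[[dir]] <- stage("similarity-test", if (dir == "1->2")
        similarity_test(g_n, g_i, dir, config$n_reps,
                        child_seed(config$seed, paste0("sim12-", mode)))
        else
          similarity_test(g_i, g_n, dir, config$n_reps,
                          child_seed(config$seed, paste0("sim21-", mode))))
    }
    dyn <- stage("dynamics", dynamics_indices(
      g_n, g_i, q = config$q, intersection_mode = config$intersection_mode))

    for (dir in config$directions) {
      rows[[length(rows) + 1]] <- data.frame(
        species = config$species, region = invasive_range,
        variables = mode, direction = dir,
        D = d_obs, equivalency_p = equiv$p, similarity_p = sims[[dir]]$p,
        unfilling = dyn$unfilling, expansion = dyn$expansion,
        stability = dyn$stability,
        pc12_explained = sum(pca$explained_fraction[1:2]),
        n_native = n_occurrences(occ_n), n_invasive = n_occurrences(occ_i),
        selected_vars = paste(vars, collapse = ";"))
    }
    modes[[mode]] <- list(selection = selection, pca = pca,
                          grids = list(native = g_n, invasive = g_i),
                          equivalency = equiv, similarity = sims,
                          dynamics = dyn,
                          backgrounds = list(native = bg_n,
                                             invasive = bg_i))
  }
  structure(
    list(report = do.call(rbind, rows), modes = modes,
         native_range = config$native_range, invasive_range = invasive_range,
         alpha = config$alpha, species = config$species),
    class = "niche_comparison")
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat("<niche_comparison> ", x$species, ": ", x$native_range, " vs ",
      x$invasive_range, "\n", sep = "")
  print(x$report[, c("region", "variables", "direction", "D",
                     "similarity_p", "unfilling", "expansion", "stability")],
        row.names = FALSE)
  invisible(x)
}

#' Render comparison reports to tables and figures
#'
#' Writes one CSV per direction with the conventional seven-column layout
#' (`Region, Variables, Overlap (D), Similarity Test, Uninvaded, Expansion,
#' Stability`; similarity p-values significant at `alpha` are starred), a
#' machine-readable JSON of all rows, per-contrast niche density figures with
#' the 50%-densest (solid) and full available (dashed) contours, and a PCA
#' correlation circle per variable mode.
#'
#' @param comparisons a `niche_comparison` or list of them (one per invasive
#'   range).
#' @param out_dir output directory.
#' @param alpha significance level for starring (default: from the
#'   comparisons).
#' @param figures whether to render PNG figures.
#' @return invisibly, the paths written.
#' @export
render_report <- function(comparisons, out_dir, alpha = NULL,
                          figures = TRUE) {
  if (inherits(comparisons, "niche_comparison"))
    comparisons <- list(comparisons)
  if (length(comparisons) == 0) stop("empty contrast list", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(alpha)) alpha <- comparisons[[1]]$alpha
  report <- do.call(rbind, lapply(comparisons, `[[`, "report"))
  paths <- character(0)

  fmt <- function(x, digits = 3) formatC(round(x, digits), format = "fg")
  for (dir in unique(report$direction)) {
    sub <- report[report$direction == dir, ]
    tab <- data.frame(
      Region = sub$region,
      Variables = ifelse(sub$variables == "all", "All", "Selected"),
      `Overlap (D)` = fmt(sub$D),
      `Similarity Test` = paste0(fmt(sub$similarity_p),
                                 ifelse(sub$similarity_p < alpha, " *", "")),
      Uninvaded = fmt(sub$unfilling),
      Expansion = fmt(sub$expansion),
      Stability = fmt(sub$stability),
      check.names = FALSE)
    p <- file.path(out_dir, paste0("niche_table_",
                                   gsub("[^0-9a-z]+", "", dir), ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(out_dir, "niche_report.json")
  jsonlite::write_json(report, pj, dataframe = "rows", digits = NA)
  paths <- c(paths, pj)

  if (figures) {
    for (cmp in comparisons) {
      for (mode in names(cmp$modes)) {
        m <- cmp$modes[[mode]]
        pf <- file.path(out_dir, sprintf("niche_%s_%s_%s.png",
                                         cmp$species, cmp$invasive_range,
                                         mode))
        ggplot2::ggsave(pf, plot_niche_grids(
          m$grids, c(cmp$native_range, cmp$invasive_range)),
          width = 7, height = 6, dpi = 120)
        pc <- file.path(out_dir, sprintf("pca_circle_%s_%s_%s.png",
                                         cmp$species, cmp$invasive_range,
                                         mode))
        ggplot2::ggsave(pc, plot_correlation_circle(m$pca),
                        width = 6, height = 6, dpi = 120)
        paths <- c(paths, pf, pc)
      }
    }
  }
  invisible(paths)
}

# density level enclosing the top `mass` share of a surface
density_level <- function(z, mass = 0.5) {
  s <- sort(as.numeric(z), decreasing = TRUE)
  cum <- cumsum(s)
  s[max(1L, which(cum >= mass * sum(s))[1])]
}

#' Plot corrected occupancy grids of a range pair
#'
#' Shaded corrected occupancy per range with the 50% densest niche (solid) and
#' the full available environment (dashed) contours, in PC1-PC2 space.
#'
#' @param grids named list of two `niche_grid` objects.
#' @param labels range labels for the legend.
#' @return a ggplot object.
#' @export
plot_niche_grids <- function(grids, labels = names(grids)) {
  long <- do.call(rbind, lapply(seq_along(grids), function(i) {
    g <- grids[[i]]
    data.frame(x = rep(g$x, times = g$R), y = rep(g$y, each = g$R),
               z = as.numeric(g$z), range = labels[i])
  }))
  contour_df <- function(g, m, level, label) {
    if (max(m) <= level || min(m) >= level) return(NULL)
    cl <- grDevices::contourLines(g$x, g$y, m, levels = level)
    if (length(cl) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(cl), function(k)
      data.frame(x = cl[[k]]$x, y = cl[[k]]$y,
                 piece = k, range = label)))
  }
  solid <- do.call(rbind, lapply(seq_along(grids), function(i)
    contour_df(grids[[i]], grids[[i]]$z,
               density_level(grids[[i]]$z, 0.5), labels[i])))
  dashed <- do.call(rbind, lapply(seq_along(grids), function(i) {
    e <- grids[[i]]$e
    if (!any(e == 0)) return(NULL)  # available everywhere: no boundary
    contour_df(grids[[i]], e, min(e[e > 0]) / 2, labels[i])
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$z, fill = .data$range)) +
    ggplot2::scale_alpha_continuous(range = c(0, 0.9), guide = "none") +
    ggplot2::labs(x = "PC1", y = "PC2", fill = "Range", colour = "Range") +
    ggplot2::theme_minimal()
  if (!is.null(solid))
    p <- p + ggplot2::geom_path(
      data = solid,
      ggplot2::aes(group = interaction(.data$range, .data$piece),
                   colour = .data$range), linewidth = 0.6)
  if (!is.null(dashed))
    p <- p + ggplot2::geom_path(
      data = dashed,
      ggplot2::aes(group = interaction(.data$range, .data$piece),
                   colour = .data$range), linetype = "dashed",
                   linewidth = 0.4)
  p
}

#' Correlation circle of a PCA space
#' @param pca a `pca_space`.
#' @return a ggplot object.
#' @export
plot_correlation_circle <- function(pca) {
  ld <- pca$loadings[, 1:2, drop = FALSE]
  arrows <- data.frame(var = rownames(ld),
                       x = ld[, 1] * sqrt(pca$explained_fraction[1] *
                                            nrow(ld)),
                       y = ld[, 2] * sqrt(pca$explained_fraction[2] *
                                            nrow(ld)))
  scale <- max(sqrt(arrows$x^2 + arrows$y^2))
  arrows$x <- arrows$x / scale; arrows$y <- arrows$y / scale
  circ <- data.frame(x = cos(seq(0, 2 * pi, length.out = 200)),
                     y = sin(seq(0, 2 * pi, length.out = 200)))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                       colour = "grey60") +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          arrow = ggplot2::arrow(length =
                                                   ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = arrows,
                       ggplot2::aes(.data$x * 1.08, .data$y * 1.08,
                                    label = .data$var), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$explained_fraction[2])) +
    ggplot2::theme_minimal()
}
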