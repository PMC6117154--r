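#' Run one declared analysis against the emitted tables.
#' @noRd
run_report_analysis <- function(spec, tables) {
  tab_name <- spec$table
  if (is.null(tab_name) || is.null(tables[[tab_name]])) {
    stop_contract("missing upstream stage: ", tab_name %||% "<unnamed table>")
  }
  df <- tables[[tab_name]]
  switch(
    spec$type,
    correlation = {
      r <- correlate_sleep_vs_responsiveness(df[[spec$x]], df[[spec$y]],
                                             window = spec$window %||% "day")
      list(type = "correlation", table = tab_name, x = spec$x, y = spec$y,
           window = r$window, R = r$R, p = r$p, n = r$n,
           n_excluded = r$n_excluded)
    },
    wilcoxon_vs_zero = {
      g <- compare_conditions(df[[spec$value]],
                              list(test = "wilcoxon_signed_rank_vs_zero"))
      c(list(type = "wilcoxon_vs_zero", table = tab_name,
             value = spec$value), unclass_comparison(g))
    },
    two_group = {
      groups <- split(df[[spec$value]], df[[spec$group]])
      if (length(groups) != 2) stop_contract("two_group needs two levels")
      g <- compare_conditions(unname(groups),
                              list(test = spec$test %||% "mann_whitney"))
      c(list(type = "two_group", table = tab_name, value = spec$value,
             group = spec$group, levels = names(groups)),
        unclass_comparison(g))
    },
    paired = {
      wide <- reshape_pairs(df, spec)
      g <- compare_conditions(wide, list(test = spec$test %||% "paired_t",
                                         normality_screen = spec$normality_screen))
      c(list(type = "paired", table = tab_name, value = spec$value,
             conditions = colnames(wide)), unclass_comparison(g))
    },
    friedman_dunn = {
      wide <- reshape_pairs(df, spec)
      g <- compare_conditions(wide, list(test = "friedman_dunn",
                                         reference = spec$reference))
      c(list(type = "friedman_dunn", table = tab_name, value = spec$value,
             reference = spec$reference %||% colnames(wide)[1]),
        unclass_comparison(g))
    },
    two_way_anova_dunnett = {
      g <- compare_conditions(
        data.frame(value = df[[spec$value]], group = df[[spec$group]],
                   f2 = df[[spec$factor2]]),
        list(test = "two_way_anova_dunnett", reference = spec$reference,
             factor2 = "f2"))
      c(list(type = "two_way_anova_dunnett", table = tab_name,
             value = spec$value, group = spec$group), unclass_comparison(g))
    },
    stop_contract("unknown analysis type: ", spec$type)
  )
}

#' @noRd
unclass_comparison <- function(g) {
  out <- unclass(g)
  if (!is.null(out$normality)) out$normality <- as.list(out$normality)
  if (!is.null(out$contrasts)) {
    out$contrasts <- lapply(seq_len(nrow(out$contrasts)), function(i) {
      as.list(out$contrasts[i, ])
    })
  }
  out
}

#' Long (id, condition, value) table to a wide subjects x conditions matrix.
#' @noRd
reshape_pairs <- function(df, spec) {
  id <- spec$id %||% "id"
  cond <- spec$condition %||% "condition"
  val <- spec$value %||% "value"
  wide <- stats::reshape(df[, c(id, cond, val)], idvar = id,
                         timevar = cond, direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub(paste0("^", val, "\\."), "", colnames(mat))
  if (!is.null(spec$condition_order)) {
    mat <- mat[, spec$condition_order, drop = FALSE]
  }
  if (anyNA(mat)) stop_contract("paired design has missing cells")
  mat
}

#' Assemble a report bundle of tables, statistics and figures
#'
#' Writes every table as a tidy CSV, runs the declared analyses against those
#' same tables (so every reported p-value is reproducible from the emitted
#' files), writes the complete statistics as JSON, and draws standard figures
#' for tables following the package's column conventions. Deterministic given
#' identical inputs: rerunning produces byte-identical CSV and JSON.
#'
#' @param tables Named list of data frames (the per-observation tables).
#' @param analyses Named list of analysis specifications; each is a list with
#'   `type` (one of `"correlation"`, `"wilcoxon_vs_zero"`, `"two_group"`,
#'   `"paired"`, `"friedman_dunn"`, `"two_way_anova_dunnett"`), `table` (the
#'   name of the table it reads) and the type's column arguments (see
#'   [run_report_analysis] sources or the vignette).
#' @param out_dir Output directory (created if needed).
#' @param required Character vector of table names that must be present;
#'   a missing one raises a dependency error naming the stage.
#' @param plots Draw figures (PNG) for recognised tables; failures to open a
#'   graphics device degrade to a warning.
#' @return Invisibly, a list with `stats` (the analysis results) and `paths`
#'   (files written).
#' @export
build_report <- function(tables, analyses = list(), out_dir,
                         required = NULL, plots = TRUE) {
  for (nm in required) {
    if (is.null(tables[[nm]])) stop_contract("missing upstream stage: ", nm)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  stats <- lapply(analyses, run_report_analysis, tables = tables)
  jp <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, jp, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  paths <- c(paths, jp)
  if (plots) {
    paths <- c(paths, report_plots(tables, out_dir))
  }
  invisible(list(stats = stats, paths = paths))
}

#' Standard figures for tables following the package column conventions.
#' @noRd
report_plots <- function(tables, out_dir) {
  pdir <- file.path(out_dir, "plots")
  dir.create(pdir, showWarnings = FALSE)
  written <- character(0)
  save_plot <- function(p, name) {
    f <- file.path(pdir, paste0(name, ".png"))
    ok <- tryCatch({
      ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
      TRUE
    }, error = function(e) {
      warning("could not draw ", name, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, f)
  }
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (all(c("zt", "min_per_hr") %in% names(df))) {
      agg <- aggregate(min_per_hr ~ zt, df, mean)
      save_plot(
        ggplot2::ggplot(agg, ggplot2::aes(x = zt, y = min_per_hr)) +
          ggplot2::geom_line() + ggplot2::geom_point() +
          ggplot2::labs(x = "ZT (h)", y = "Sleep (min/hr)", title = nm),
        nm)
    } else if (all(c("t_rel", "speed") %in% names(df))) {
      save_plot(
        ggplot2::ggplot(df, ggplot2::aes(x = t_rel, y = speed)) +
          ggplot2::geom_line() +
          ggplot2::geom_vline(xintercept = 0, linetype = 2) +
          ggplot2::labs(x = "Time from stimulus (s)", y = "Speed (mm/s)",
                        title = nm),
        nm)
    } else if (all(c("bin_lo_min", "fraction") %in% names(df))) {
      dd <- df[is.finite(df$bin_hi_min), , drop = FALSE]
      save_plot(
        ggplot2::ggplot(dd, ggplot2::aes(x = factor(bin_lo_min), y = fraction)) +
          ggplot2::geom_col() +
          ggplot2::labs(x = "Prior immobility bin (min)",
                        y = "Fraction responding", title = nm),
        nm)
    } else if (all(c("condition", "dvm") %in% names(df))) {
      save_plot(
        ggplot2::ggplot(df, ggplot2::aes(x = condition, y = dvm)) +
          ggplot2::geom_boxplot() +
          ggplot2::labs(x = NULL, y = expression(Delta * V[m] ~ "(mV)"),
                        title = nm),
        nm)
    }
  }
  written
}
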