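# Nest density and occupancy per land-cover class from 10 x 10 m plot
# surveys, plus the class comparison test.

#' Summarize plot surveys into per-class density and occupancy
#'
#' Plots are 10 x 10 m (0.01 ha), so class density in nests/ha is
#' `100 * total_nests / n_plots`, reported as a half-up-rounded integer;
#' occupancy is the fraction of plots holding at least one nest, reported to
#' two decimals. Rounding happens *here*, before any extrapolation: the
#' national table is defined in terms of these reported values.
#'
#' @param table plot-survey data.frame with columns `class`, `plot_id`,
#'   `nests` (see [read_plot_table()]).
#' @return data.frame with one row per surveyed class: `class`, `n_plots`,
#'   `n_nests`, `density` (nests/ha), `occupancy`, `provenance`
#'   (= "surveyed").
#' @export
summarize_plots <- function(table) {
  table <- validate_plot_table(table)
  by_class <- split(table, table$class)
  rows <- lapply(by_class, function(d) {
    data.frame(class = d$class[1], n_plots = nrow(d),
               n_nests = sum(d$nests),
               density = round_half_up(100 * sum(d$nests) / nrow(d)),
               occupancy = round_half_up(mean(d$nests >= 1), 2),
               provenance = "surveyed", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  log_info("summarize_plots: %d classes, %d plots, %d nests",
           nrow(out), sum(out$n_plots), sum(out$n_nests))
  out
}

#' Nominal and zero density estimates for unsurveyed classes
#'
#' Low-preference ("nominal") classes are assigned a nominal density of
#' 3 nests/ha and occupancy 0.03 without field surveys; unsuitable classes
#' get zero for both.
#'
#' @param classes character vector of class codes to assign.
#' @param class_table a category map with columns `code`, `category`
#'   (default [default_class_table()]); `surveyed` classes may not appear in
#'   `classes`.
#' @param nominal_density,nominal_occupancy the nominal values
#'   (defaults 3 nests/ha and 0.03).
#' @return data.frame in the same shape as [summarize_plots()] output, with
#'   `provenance` "nominal" or "unsuitable" and `n_plots`/`n_nests` 0.
#' @export
assign_nominal <- function(classes, class_table = default_class_table(),
                           nominal_density = 3, nominal_occupancy = 0.03) {
  if (!length(classes)) {
    return(data.frame(class = character(), n_plots = integer(),
                      n_nests = integer(), density = numeric(),
                      occupancy = numeric(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  cat_of <- class_table$category[match(classes, class_table$code)]
  if (any(is.na(cat_of)))
    stop("configuration error: unknown class code(s): ",
         paste(classes[is.na(cat_of)], collapse = ", "))
  if (any(cat_of == "surveyed"))
    stop("configuration error: class(es) ",
         paste(classes[cat_of == "surveyed"], collapse = ", "),
         " are categorized as surveyed and cannot take nominal values")
  data.frame(class = classes, n_plots = 0L, n_nests = 0L,
             density = ifelse(cat_of == "nominal", nominal_density, 0),
             occupancy = ifelse(cat_of == "nominal", nominal_occupancy, 0),
             provenance = cat_of, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across land-cover classes
#'
#' Tie-corrected Kruskal-Wallis test on per-plot nest counts (nest counts
#' are heavily tied at zero, so the tie correction matters). All-tied data
#' yield H = 0, p = 1. The chi-square approximation with `k - 1` degrees of
#' freedom is used throughout.
#'
#' @param groups list of numeric vectors, one per class (>= 2 groups, each
#'   non-empty).
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("input error: need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("input error: empty group")
  x <- unlist(groups)
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
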