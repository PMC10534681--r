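#' One-way ANOVA across formulations
#'
#' Classical fixed-effects one-way analysis of variance of penetrated
#' amount on formulation, fitted for a single experimental arm.  The
#' model is fitted with \code{stats::lm()}/\code{anova()}; the result
#' collects the F statistic, degrees of freedom, p value and group
#' means.
#'
#' @param records a \code{data.frame} of permeation records for one
#'   arm (columns \code{response} and \code{group}).
#' @param response,group column names of the response and grouping
#'   variables (defaults match [generate_permeation_dataset()]).
#' @return an object of class \code{"anova_result"} with elements
#'   \code{F}, \code{df_between}, \code{df_within}, \code{p},
#'   \code{group_means}, \code{group_n}, \code{ms_within}.
#' @export
one_way_anova <- function(records, response = "amount_ug_per_cm2",
                          group = "formulation") {
  missing <- setdiff(c(response, group), names(records))
  if (length(missing))
    .fail("records lack column(s): ", paste(missing, collapse = ", "))
  y <- records[[response]]
  g <- factor(records[[group]])
  if (nlevels(g) < 2) .fail("need at least 2 groups for an ANOVA")
  n_per <- table(g)
  if (any(n_per < 2)) .fail("every group needs at least 2 replicates")
  if (stats::var(y) == 0)
    .fail("degenerate input: all values identical (zero total variance)")
  an <- stats::anova(stats::lm(y ~ g))
  gm <- tapply(y, g, mean)
  gm <- stats::setNames(as.numeric(gm), names(gm))
  structure(list(F = an$`F value`[1],
                 df_between = an$Df[1],
                 df_within = an$Df[2],
                 p = an$`Pr(>F)`[1],
                 group_means = gm,
                 group_n = as.vector(n_per),
                 ms_within = an$`Mean Sq`[2]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(round(x$group_means, 4))
  invisible(x)
}

# significance stars used throughout the comparison report
.stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' All-pairs multiple comparisons
#'
#' Post hoc pairwise contrasts between formulations after a one-way
#' ANOVA.  The default is Tukey's HSD on the pooled within-group
#' variance (\code{stats::TukeyHSD()}); Games-Howell, which drops the
#' equal-variance assumption by Welch-type studentization, is
#' available for heteroscedastic cells.  Two significance tiers are
#' starred (* p < 0.05, ** p < 0.01).
#'
#' @inheritParams one_way_anova
#' @param method \code{"tukey"} (default) or \code{"games_howell"}.
#' @return a \code{data.frame} of class \code{"pairwise_comparisons"}
#'   with columns \code{group1}, \code{group2}, \code{diff},
#'   \code{p_adj}, \code{stars}.
#' @export
multiple_comparisons <- function(records, response = "amount_ug_per_cm2",
                                 group = "formulation",
                                 method = c("tukey", "games_howell")) {
  method <- match.arg(method)
  missing <- setdiff(c(response, group), names(records))
  if (length(missing))
    .fail("records lack column(s): ", paste(missing, collapse = ", "))
  y <- records[[response]]
  g <- factor(records[[group]])
  if (nlevels(g) < 2) .fail("need at least 2 groups")
  if (any(table(g) < 2)) .fail("every group needs at least 2 replicates")
  if (all(tapply(y, g, stats::var) == 0))
    .fail("degenerate input: zero within-group variance")
  out <- if (method == "tukey") {
    hsd <- stats::TukeyHSD(stats::aov(y ~ g))$g
    pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
    data.frame(group1 = vapply(pairs, `[`, "", 1),
               group2 = vapply(pairs, `[`, "", 2),
               diff = hsd[, "diff"],
               p_adj = hsd[, "p adj"])
  } else {
    .games_howell(y, g)
  }
  out$stars <- .stars(out$p_adj)
  rownames(out) <- NULL
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

# Games-Howell: pairwise Welch t with studentized-range reference
.games_howell <- function(y, g) {
  lev <- levels(g)
  m <- tapply(y, g, mean); v <- tapply(y, g, stats::var); n <- tapply(y, g, length)
  combs <- utils::combn(lev, 2)
  do.call(rbind, apply(combs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    data.frame(group1 = j, group2 = i, diff = unname(m[j] - m[i]),
               p_adj = stats::ptukey(q, length(lev), df, lower.tail = FALSE))
  }))
}

#' Static/dynamic overestimation ratios
#'
#' For each formulation, the ratio of the mean penetrated amount in
#' the static Franz-cell arm to that in the dynamic tear-flow arm.  A
#' static assay keeps the formulation on the cornea for the whole run,
#' so ratios well above 1 quantify how much the static protocol
#' overestimates penetration relative to the washout-limited dynamic
#' protocol.
#'
#' @param static_records,dynamic_records record tables for the two
#'   arms; every formulation must appear in both.
#' @param response column holding the penetrated amount.
#' @return a \code{data.frame} with columns \code{formulation},
#'   \code{mean_static}, \code{mean_dynamic}, \code{ratio}.
#' @export
overestimation_ratios <- function(static_records, dynamic_records,
                                  response = "amount_ug_per_cm2") {
  ms <- tapply(static_records[[response]], static_records$formulation, mean)
  md <- tapply(dynamic_records[[response]], dynamic_records$formulation, mean)
  missing <- union(setdiff(names(ms), names(md)), setdiff(names(md), names(ms)))
  if (length(missing))
    .fail("formulation(s) missing from one arm: ",
          paste(missing, collapse = ", "))
  md <- md[names(ms)]
  if (any(md <= 0)) .fail("dynamic means must be positive")
  data.frame(formulation = names(ms),
             mean_static = as.vector(ms),
             mean_dynamic = as.vector(md),
             ratio = as.vector(ms / md),
             row.names = NULL)
}

#' Run the full static-vs-dynamic comparison pipeline
#'
#' End-to-end analysis: per-arm one-way ANOVA, all-pairs post hoc
#' comparisons at alpha = 0.05 with two starred tiers, and
#' per-formulation static/dynamic overestimation ratios.  Arms are
#' analysed separately — static and dynamic runs differ in apparatus
#' and temperature, so no pooled two-way model is attempted.
#'
#' @param x an [experiment_design()] (records are generated from its
#'   seed), a permeation record \code{data.frame}, or a path to a
#'   records CSV as written by [write_permeation()].
#' @param method post hoc procedure, see [multiple_comparisons()].
#' @return an object of class \code{"comparison_report"}: a list with
#'   \code{anova} (per-arm [one_way_anova()] results),
#'   \code{pairwise} (per-arm comparison tables), \code{ratios},
#'   \code{seed} (when known) and \code{settings}.
#' @examples
#' rep <- run_pipeline(experiment_design(seed = 7))
#' rep$ratios
#' @export
run_pipeline <- function(x, method = "tukey") {
  seed <- NA_integer_
  if (inherits(x, "experiment_design")) {
    seed <- x$seed
    records <- generate_permeation_dataset(x)
  } else if (is.character(x)) {
    records <- read_permeation(x)
  } else if (is.data.frame(x)) {
    missing <- setdiff(c("formulation", "model", "replicate",
                         "amount_ug_per_cm2"), names(x))
    if (length(missing))
      .fail("permeation records lack column(s): ",
            paste(missing, collapse = ", "))
    records <- x
  } else .fail("x must be an experiment_design, a data.frame or a CSV path")
  if (!is.na(s <- attr(records, "seed") %||% NA_integer_)) seed <- s
  arms <- split(records, records$model)
  if (!all(c("static", "dynamic") %in% names(arms)))
    .fail("records must contain both a static and a dynamic arm")
  structure(list(
    anova = lapply(arms, one_way_anova),
    pairwise = lapply(arms, multiple_comparisons, method = method),
    ratios = overestimation_ratios(arms$static, arms$dynamic),
    seed = seed,
    settings = list(alpha = 0.05, method = method)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (arm in names(x$anova)) {
    cat("==", arm, "arm ==\n")
    print(x$anova[[arm]])
    sig <- x$pairwise[[arm]][x$pairwise[[arm]]$p_adj < 0.05, ]
    cat(nrow(x$pairwise[[arm]]), "pairwise comparisons,",
        nrow(sig), "significant at alpha = 0.05\n")
    if (nrow(sig)) print(sig, row.names = FALSE)
  }
  cat("== static/dynamic overestimation ==\n")
  print(transform(x$ratios, ratio = round(ratio, 2)), row.names = FALSE)
  if (!is.na(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' Write a comparison report to JSON
#'
#' @param report a [run_pipeline()] result.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  out <- list(
    seed = report$seed,
    settings = report$settings,
    anova = lapply(report$anova, function(a)
      list(F = a$F, df_between = a$df_between, df_within = a$df_within,
           p = a$p, group_means = as.list(a$group_means))),
    pairwise = lapply(report$pairwise, as.data.frame),
    overestimation = report$ratios)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
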