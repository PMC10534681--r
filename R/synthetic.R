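#' Default formulation panel
#'
#' The seven-formulation comparison panel: an aqueous drug solution
#' (SOL), three poloxamer 407 gels (14, 16, 20\% w/w) and three 16\%
#' poloxamer gels with increasing chitosan (0.5, 1.0, 1.25\% w/w).
#' True mean penetrated amounts are configured per arm so that the
#' generated data reproduce the qualitative comparison pattern: in the
#' static (Franz cell) arm all formulations deliver similar amounts,
#' while in the dynamic (simulated tear flow) arm mucoadhesive
#' chitosan gels deliver about three times the poloxamer-only gels.
#' The resulting static/dynamic overestimation is about 6-fold for
#' poloxamer-only formulations and about 2-fold for chitosan gels.
#'
#' @param mean_static,mean_plx_dynamic,mean_chitosan_dynamic true mean
#'   penetrated amounts (ug/cm2) for the static arm (all
#'   formulations), the dynamic-arm poloxamer-only cells, and the
#'   dynamic-arm chitosan cells.
#' @param cv lognormal coefficient of variation shared by all cells
#'   (default 0.25).
#' @return a \code{data.frame} with one row per formulation: columns
#'   \code{name}, \code{poloxamer_pct}, \code{chitosan_pct},
#'   \code{mean_static}, \code{mean_dynamic}, \code{cv}.
#' @export
default_formulations <- function(mean_static = 3.0,
                                 mean_plx_dynamic = 0.5,
                                 mean_chitosan_dynamic = 1.5,
                                 cv = 0.25) {
  f <- data.frame(
    name = c("SOL", "PLX14", "PLX16", "PLX20",
             "PLX16C050", "PLX16C100", "PLX16C125"),
    poloxamer_pct = c(0, 14, 16, 20, 16, 16, 16),
    chitosan_pct = c(0, 0, 0, 0, 0.5, 1.0, 1.25),
    stringsAsFactors = FALSE)
  f$mean_static <- mean_static
  f$mean_dynamic <- ifelse(f$chitosan_pct > 0,
                           mean_chitosan_dynamic, mean_plx_dynamic)
  f$cv <- cv
  f
}

#' Design of a synthetic permeation experiment
#'
#' Bundles the formulation panel with the replicate structure of the
#' two arms (quintuplicate static Franz-cell runs, quadruplicate
#' dynamic tear-flow runs) and the RNG seed that makes every draw
#' reproducible.
#'
#' @param formulations a formulation table as from
#'   [default_formulations()]; must have unique names and positive
#'   means and CVs.
#' @param replicates_static,replicates_dynamic replicate counts per
#'   formulation (defaults 5 and 4).
#' @param seed integer RNG seed recorded in every output.
#' @return an object of class \code{"experiment_design"}.
#' @export
experiment_design <- function(formulations = default_formulations(),
                              replicates_static = 5,
                              replicates_dynamic = 4,
                              seed = 1L) {
  needed <- c("name", "mean_static", "mean_dynamic", "cv")
  missing <- setdiff(needed, names(formulations))
  if (length(missing))
    .fail("formulation table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(formulations$name))
    .fail("duplicate formulation names")
  if (any(formulations$mean_static <= 0) || any(formulations$mean_dynamic <= 0))
    .fail("formulation means must be positive")
  if (any(formulations$cv <= 0)) .fail("formulation cv must be positive")
  if (replicates_static < 1 || replicates_dynamic < 1)
    .fail("replicate counts must be at least 1")
  structure(list(formulations = formulations,
                 replicates_static = as.integer(replicates_static),
                 replicates_dynamic = as.integer(replicates_dynamic),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Permeation experiment design: %d formulations, %d static + %d dynamic replicates, seed %d\n",
              nrow(x$formulations), x$replicates_static,
              x$replicates_dynamic, x$seed))
  print(x$formulations, row.names = FALSE)
  invisible(x)
}

# lognormal parameterised by arithmetic mean and CV
.rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic corneal permeation dataset
#'
#' Draws replicate penetrated amounts for every formulation x arm cell
#' from a lognormal distribution with the cell's configured mean and
#' CV.  Draws are fully determined by the design seed (the caller's
#' RNG state is left untouched), so the same design always yields the
#' same records.  Cells are generated in a fixed order: static arm
#' then dynamic arm, formulations in table order.
#'
#' @param design an [experiment_design()].
#' @return a \code{data.frame} with columns \code{formulation},
#'   \code{model} (\code{"static"}/\code{"dynamic"}),
#'   \code{replicate}, \code{amount_ug_per_cm2}; the seed is attached
#'   as attribute \code{"seed"}.
#' @examples
#' d <- experiment_design(seed = 42)
#' records <- generate_permeation_dataset(d)
#' table(records$model)
#' @export
generate_permeation_dataset <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)
  f <- design$formulations
  cells <- rbind(
    data.frame(formulation = f$name, model = "static",
               mean = f$mean_static, cv = f$cv,
               n = design$replicates_static),
    data.frame(formulation = f$name, model = "dynamic",
               mean = f$mean_dynamic, cv = f$cv,
               n = design$replicates_dynamic))
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(
      formulation = formulation, model = model, replicate = seq_len(n),
      amount_ug_per_cm2 = .rlnorm_mean_cv(n, mean, cv)))
  }))
  rownames(recs) <- NULL
  attr(recs, "seed") <- design$seed
  recs
}

#' Read/write permeation records
#'
#' CSV round trip for the record table.  \code{read_permeation()}
#' validates the schema and errors naming any missing column.
#'
#' @param records a permeation record \code{data.frame}.
#' @param path CSV file.
#' @return \code{write_permeation()}: \code{path}, invisibly;
#'   \code{read_permeation()}: the validated record table.
#' @export
write_permeation <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_permeation
#' @export
read_permeation <- function(path) {
  recs <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("formulation", "model", "replicate", "amount_ug_per_cm2")
  missing <- setdiff(needed, names(recs))
  if (length(missing))
    .fail("permeation records lack column(s): ", paste(missing, collapse = ", "))
  if (any(recs$amount_ug_per_cm2 <= 0))
    .fail("penetrated amounts must be positive")
  recs
}

#' Build an experiment design from a YAML config
#'
#' The config mirrors [experiment_design()]: top-level
#' \code{replicates_static}, \code{replicates_dynamic}, \code{seed},
#' optional shared \code{cv}, and a \code{formulations} list of
#' \code{name}/\code{mean_static}/\code{mean_dynamic} (per-cell
#' \code{cv} overrides allowed).  Omitted fields fall back to the
#' package defaults.
#'
#' @param path YAML file.
#' @return an [experiment_design()].
#' @export
design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  f <- if (is.null(cfg$formulations)) default_formulations() else {
    shared_cv <- if (is.null(cfg$cv)) 0.25 else cfg$cv
    do.call(rbind, lapply(cfg$formulations, function(r)
      data.frame(name = r$name,
                 poloxamer_pct = r$poloxamer_pct %||% NA_real_,
                 chitosan_pct = r$chitosan_pct %||% NA_real_,
                 mean_static = r$mean_static,
                 mean_dynamic = r$mean_dynamic,
                 cv = r$cv %||% shared_cv)))
  }
  experiment_design(
    formulations = f,
    replicates_static = cfg$replicates_static %||% 5,
    replicates_dynamic = cfg$replicates_dynamic %||% 4,
    seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
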