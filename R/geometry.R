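#' Donor-compartment prototype geometry
#'
#' One prototype version of the dynamic model's glass donor compartment,
#' described by nine dimensions: inlet/outlet channel diameters
#' (\code{d_in}, \code{d_out}, mm), inlet/outlet heights (\code{H_in},
#' \code{H_out}, mm), the mutual flow angle \code{theta} (stored
#' categorically as \code{"right_angle"} for 90 degrees or
#' \code{"acute"}), the compartment diameter \code{D_t}, the optional
#' widened base (\code{D_b} with its start height \code{H_b}) and the
#' global height \code{H}.  A base widening requires both \code{D_b}
#' and \code{H_b}; prototypes without one have neither.
#'
#' @param version integer prototype number.
#' @param d_in,d_out inlet/outlet channel diameters (mm); the outlet is
#'   larger than the inlet to avoid induced pressure.
#' @param H_in,H_out inlet/outlet heights (mm).
#' @param theta \code{"right_angle"} or \code{"acute"}.
#' @param D_t donor compartment diameter (mm).
#' @param H global height (mm).
#' @param D_b,H_b base diameter and base-widening start height (mm),
#'   both present or both absent (\code{NA}).
#' @return a one-row \code{data.frame} of class \code{"donor_geometry"}.
#' @export
donor_geometry <- function(version, d_in, d_out, H_in, H_out, theta,
                           D_t, H, D_b = NA_real_, H_b = NA_real_) {
  theta <- match.arg(theta, c("right_angle", "acute"))
  dims <- c(d_in = d_in, d_out = d_out, H_in = H_in, H_out = H_out,
            D_t = D_t, H = H)
  if (any(!is.finite(dims)) || any(dims <= 0))
    .fail("all dimensions must be positive: ",
          paste(names(dims)[!is.finite(dims) | dims <= 0], collapse = ", "))
  if (is.na(D_b) != is.na(H_b))
    .fail("D_b and H_b must be both present or both absent")
  if (!is.na(D_b) && (D_b <= 0 || H_b <= 0))
    .fail("D_b and H_b must be positive when present")
  structure(
    data.frame(version = as.integer(version), d_in = d_in, d_out = d_out,
               H_in = H_in, H_out = H_out, theta = theta, D_t = D_t,
               D_b = D_b, H_b = H_b, H = H),
    class = c("donor_geometry", "data.frame"))
}

#' Load the donor-compartment prototype table
#'
#' Reads the packaged table of the five glass prototype versions (or a
#' user CSV in the same layout).  The file stores the angle as
#' \code{"90"} / \code{"<90"} and absent base dimensions as empty
#' cells, exactly as tabulated; printed ratio columns
#' (\code{d_out_d_in}, \code{H_in_H_out}), when present, are kept for
#' cross-checking against [derived_ratios()].
#'
#' @param path CSV file; default is the packaged prototype table.
#' @return a \code{data.frame} of class \code{"donor_geometry"}, one
#'   row per version, with \code{theta} recoded to
#'   \code{"right_angle"}/\code{"acute"}.
#' @export
donor_geometry_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "donor_versions.csv", package = "lacriflow",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("version", "d_in", "d_out", "H_in", "H_out", "theta",
              "D_t", "D_b", "H_b", "H")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    .fail("prototype table lacks column(s): ", paste(missing, collapse = ", "))
  tab$theta <- ifelse(trimws(tab$theta) == "90", "right_angle", "acute")
  if (any(tab$d_out <= tab$d_in))
    .fail("every prototype must have d_out > d_in")
  if (any(is.na(tab$D_b) != is.na(tab$H_b)))
    .fail("D_b and H_b must be both present or both absent in every row")
  class(tab) <- c("donor_geometry", "data.frame")
  tab
}

#' Derived channel and height ratios
#'
#' Computes \code{d_out/d_in} and \code{H_in/H_out} for each prototype,
#' truncated (floored, not rounded) at two decimals.  Truncation is the
#' convention that reproduces every tabulated ratio (10.8/11.5 =
#' 0.9391 is printed 0.93, and 5.00/2.43 = 2.0576 is printed 2.05).
#'
#' @param geometry a \code{donor_geometry} row or table.
#' @return a \code{data.frame} with columns \code{version},
#'   \code{d_out_d_in}, \code{H_in_H_out}.
#' @export
derived_ratios <- function(geometry) {
  g <- as.data.frame(geometry)
  denom <- c(g$d_in, g$H_out)
  if (any(!is.finite(denom)) || any(denom <= 0))
    .fail("ratio denominators (d_in, H_out) must be positive")
  data.frame(version = g$version,
             d_out_d_in = trunc2(g$d_out / g$d_in),
             H_in_H_out = trunc2(g$H_in / g$H_out))
}

#' Rank donor-compartment prototypes
#'
#' Codifies the selection logic for the final prototype: only versions
#' with an acute flow angle and a widened base avoid fluid damming and
#' seat the eyeball, so candidates are filtered to those, then ranked
#' by the inlet/outlet height gap \code{H_in/H_out} (descending — a
#' larger gap drains the dammed fluid), with ties broken by larger
#' \code{H_b} and then by lower version number.  On the five shipped
#' prototypes this selects version 5.
#'
#' @param candidates a \code{donor_geometry} table (non-empty).
#' @return an object of class \code{"version_ranking"}: a list with
#'   \code{ranking} (the eligible candidates in rank order, with their
#'   ratios), \code{selected} (winning version number) and
#'   \code{excluded} (versions failing the filter).
#' @export
rank_versions <- function(candidates) {
  g <- as.data.frame(candidates)
  if (nrow(g) == 0L) .fail("no candidate geometries given")
  eligible <- g$theta == "acute" & !is.na(g$D_b)
  elig <- g[eligible, , drop = FALSE]
  if (nrow(elig) == 0L)
    .fail("no candidate has both an acute flow angle and a widened base")
  ratios <- derived_ratios(elig)
  ord <- order(-ratios$H_in_H_out, -elig$H_b, elig$version)
  ranking <- cbind(elig[ord, , drop = FALSE],
                   H_in_H_out = ratios$H_in_H_out[ord])
  rownames(ranking) <- NULL
  structure(list(ranking = ranking,
                 selected = ranking$version[1],
                 excluded = g$version[!eligible]),
            class = "version_ranking")
}

#' @export
print.version_ranking <- function(x, ...) {
  cat("Donor-compartment version ranking (acute angle + widened base):\n")
  print(x$ranking[, c("version", "H_in_H_out", "H_b")], row.names = FALSE)
  if (length(x$excluded))
    cat("Excluded by filter:", paste(x$excluded, collapse = ", "), "\n")
  cat("Selected version:", x$selected, "\n")
  invisible(x)
}
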