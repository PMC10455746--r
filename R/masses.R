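#' Coating efficiency of a polymer-impregnated scaffold
#'
#' The coating efficiency (CE) is the polymer mass fraction of the coated
#' scaffold, computed from the weight gained during coating:
#' \deqn{CE\% = 100 \cdot \frac{w_{after} - w_{before}}{w_{after}}}
#' The polymer content (`w_after - w_before`) is always recomputed from the
#' two weighings, never taken from a pre-tabulated content column, so the
#' arithmetic is self-consistent.
#'
#' @param weight_before scaffold weight before coating, g.
#' @param weight_after scaffold weight after coating, g; must be >= and
#'   paired with `weight_before` (both are recycled vectorwise).
#' @return coating efficiency in percent, in `[0, 100)`.
#' @examples
#' coating_efficiency(3.157, 3.684) # 14.3 %
#' @export
coating_efficiency <- function(weight_before, weight_after) {
  if (!is.numeric(weight_before) || !is.numeric(weight_after))
    stop_field("weights", "must be numeric")
  if (length(weight_before) != length(weight_after))
    stop_field("weights", "before/after vectors must have equal length")
  if (any(!is.finite(weight_before)) || any(!is.finite(weight_after)))
    stop_field("weights", "must be finite")
  if (any(weight_before < 0))
    stop_field("weight_before", "must be >= 0")
  if (any(weight_after < weight_before))
    stop_field("weight_after", "must be >= weight_before")
  if (any(weight_after == 0))
    stop("undefined ratio: weight_after is zero", call. = FALSE)
  100 * (weight_after - weight_before) / weight_after
}

#' Water absorption capacity of a wetted scaffold
#'
#' WAC is the water mass fraction of the wet scaffold, a proxy for retained
#' open porosity after coating:
#' \deqn{WAC\% = 100 \cdot \frac{w_{wet} - w_{dry}}{w_{wet}}}
#'
#' @param dry_weight dry weight, g.
#' @param wet_weight wet weight, g, >= `dry_weight` (recycled vectorwise).
#' @return water absorption capacity in percent, in `[0, 100)`.
#' @examples
#' water_absorption_capacity(0.285, 0.328) # 13.1 %
#' @export
water_absorption_capacity <- function(dry_weight, wet_weight) {
  if (!is.numeric(dry_weight) || !is.numeric(wet_weight))
    stop_field("weights", "must be numeric")
  if (length(dry_weight) != length(wet_weight))
    stop_field("weights", "dry/wet vectors must have equal length")
  if (any(!is.finite(dry_weight)) || any(!is.finite(wet_weight)))
    stop_field("weights", "must be finite")
  if (any(dry_weight < 0))
    stop_field("dry_weight", "must be >= 0")
  if (any(wet_weight < dry_weight))
    stop_field("wet_weight", "must be >= dry_weight")
  if (any(wet_weight == 0))
    stop("undefined ratio: wet_weight is zero", call. = FALSE)
  100 * (wet_weight - dry_weight) / wet_weight
}

#' Batch summary of coating efficiencies
#'
#' Per-row CE plus the batch mean and sample SD, the "mean coating
#' efficiency" line of a coating run.
#'
#' @param batch a coating batch: a data.frame with columns
#'   `weight_before_g` and `weight_after_g` (as read by
#'   [read_coating_table()] or built by [gen_mass_table()]).
#' @return a [group_summary] of the per-row CE percentages, with the per-row
#'   values attached as attribute `ce`.
#' @export
batch_ce_summary <- function(batch) {
  if (!is.data.frame(batch) ||
      !all(c("weight_before_g", "weight_after_g") %in% names(batch)))
    stop_field("batch", "needs columns weight_before_g, weight_after_g")
  if (nrow(batch) < 2L)
    stop("sample SD undefined for fewer than 2 rows", call. = FALSE)
  ce <- coating_efficiency(batch$weight_before_g, batch$weight_after_g)
  out <- group_summary(ce, label = "coating efficiency [%]")
  attr(out, "ce") <- ce
  out
}

#' Group summary of water absorption capacities
#'
#' @param x either a numeric vector of WAC percentages (e.g. a printed
#'   table column) or a data.frame with columns `dry_g` and `wet_g` from
#'   which WAC is recomputed.
#' @return a [group_summary] with per-sample WAC attached as attribute
#'   `wac`.
#' @export
wac_group_summary <- function(x) {
  wac <- if (is.data.frame(x)) {
    if (!all(c("dry_g", "wet_g") %in% names(x)))
      stop_field("x", "needs columns dry_g, wet_g")
    water_absorption_capacity(x$dry_g, x$wet_g)
  } else if (is.numeric(x)) {
    x
  } else {
    stop_field("x", "must be a data.frame or numeric vector")
  }
  if (length(wac) < 2L)
    stop("sample SD undefined for fewer than 2 values", call. = FALSE)
  out <- group_summary(wac, label = "WAC [%]")
  attr(out, "wac") <- wac
  out
}

#' Read a coating mass-balance table
#'
#' CSV with header `series,syringe,n_pieces,weight_before_g,weight_after_g`
#' (dot decimal separator). Extra columns (e.g. a printed CE column kept for
#' cross-checking) are preserved.
#'
#' @param path file path.
#' @return data.frame, one row per syringe batch.
#' @export
read_coating_table <- function(path) {
  tab <- utils::read.csv(check_file(path), stringsAsFactors = FALSE)
  need <- c("series", "syringe", "n_pieces", "weight_before_g", "weight_after_g")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("coating table %s is missing columns: %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(tab) == 0L) stop("coating table is empty", call. = FALSE)
  if (any(tab$n_pieces < 1)) stop_field("n_pieces", "must be >= 1")
  # trigger weight validation early
  coating_efficiency(tab$weight_before_g, tab$weight_after_g)
  tab
}

#' Read a water-absorption table
#'
#' CSV with header `sample,dry_g,wet_g`; extra columns are preserved.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_wac_table <- function(path) {
  tab <- utils::read.csv(check_file(path), stringsAsFactors = FALSE)
  need <- c("sample", "dry_g", "wet_g")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("WAC table %s is missing columns: %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(tab) == 0L) stop("WAC table is empty", call. = FALSE)
  water_absorption_capacity(tab$dry_g, tab$wet_g)
  tab
}
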