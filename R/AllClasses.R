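#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

LOBE_CODES <- c("FR", "PA", "TE", "ME", "OC", "SU", "CE")

#' ParcellationScheme: region indices, names, lobes and display order
#'
#' Describes an anatomical parcellation: contiguous 1-based region indices,
#' region names, a 7-lobe assignment (frontal FR, parietal PA, temporal TE,
#' medial temporal ME, occipital OC, subcortical SU, cerebellar CE) and a
#' display ordering (a permutation of the regions) used to group the FC
#' matrix into lobe blocks. The edge enumeration of every downstream table is
#' defined under this display ordering.
#'
#' @slot regions data.frame with columns `region_index`, `region_name`,
#'   `lobe`.
#' @slot displayOrder integer permutation of `1:R`.
#' @export
setClass("ParcellationScheme",
  slots = c(regions = "data.frame", displayOrder = "integer"))

setValidity("ParcellationScheme", function(object) {
  reg <- object@regions
  msgs <- character()
  need <- c("region_index", "region_name", "lobe")
  if (!all(need %in% names(reg))) {
    return(paste("regions must have columns", paste(need, collapse = ", ")))
  }
  r <- nrow(reg)
  if (r < 1) msgs <- c(msgs, "scheme must contain at least one region")
  if (!identical(sort(reg$region_index), seq_len(r))) {
    msgs <- c(msgs, "region indices must be unique and contiguous 1..R")
  }
  if (anyDuplicated(reg$region_name)) {
    msgs <- c(msgs, "region names must be unique")
  }
  if (!all(reg$lobe %in% LOBE_CODES)) {
    msgs <- c(msgs, paste("lobe labels must be one of",
                          paste(LOBE_CODES, collapse = ", ")))
  }
  if (!identical(sort(object@displayOrder), seq_len(r))) {
    msgs <- c(msgs, "displayOrder must be a permutation of 1..R")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParcellationScheme
#'
#' @param regions data.frame with `region_index`, `region_name`, `lobe`.
#' @param displayOrder Optional integer permutation; defaults to index order.
#' @return A `ParcellationScheme`.
#' @export
ParcellationScheme <- function(regions, displayOrder = NULL) {
  regions <- as.data.frame(regions)
  regions <- regions[order(regions$region_index), , drop = FALSE]
  rownames(regions) <- NULL
  if (is.null(displayOrder)) displayOrder <- seq_len(nrow(regions))
  new("ParcellationScheme", regions = regions,
      displayOrder = as.integer(displayOrder))
}

#' Synthetic AAL-style parcellation scheme
#'
#' Builds a scheme with `nRegions` regions split over the seven lobes in
#' fixed order (FR, PA, TE, ME, OC, SU, CE), as evenly as possible. With the
#' default 116 regions this emulates the shape (not the anatomy) of the
#' 116-region AAL atlas; region names are "AAL1".."AAL116" to match the pair
#' notation used in reports.
#'
#' @param nRegions Number of regions (>= 3).
#' @param namePrefix Prefix for region names.
#' @return A `ParcellationScheme`.
#' @export
makeScheme <- function(nRegions = 116, namePrefix = "AAL") {
  if (nRegions < 3) stop("nRegions must be >= 3", call. = FALSE)
  base <- nRegions %/% 7
  sizes <- rep(base, 7)
  extra <- nRegions - base * 7
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  lobes <- rep(LOBE_CODES, times = sizes)
  ParcellationScheme(data.frame(
    region_index = seq_len(nRegions),
    region_name = paste0(namePrefix, seq_len(nRegions)),
    lobe = lobes,
    stringsAsFactors = FALSE))
}

#' @describeIn ParcellationScheme-accessors Number of regions.
#' @export
nRegions <- function(scheme) nrow(scheme@regions)

#' Accessors for ParcellationScheme
#'
#' @param scheme A `ParcellationScheme`.
#' @name ParcellationScheme-accessors
#' @return `regionNames` / `regionLobes` return character vectors in
#'   region-index order; `displayOrder` the display permutation.
NULL

#' @rdname ParcellationScheme-accessors
#' @export
regionNames <- function(scheme) scheme@regions$region_name

#' @rdname ParcellationScheme-accessors
#' @export
regionLobes <- function(scheme) scheme@regions$lobe

#' @rdname ParcellationScheme-accessors
#' @export
displayOrder <- function(scheme) scheme@displayOrder

setMethod("show", "ParcellationScheme", function(object) {
  tab <- table(factor(regionLobes(object), levels = LOBE_CODES))
  cat("ParcellationScheme with", nRegions(object), "regions\n")
  cat("  lobes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  ident <- identical(displayOrder(object), seq_len(nRegions(object)))
  cat("  display order:", if (ident) "index order" else "custom", "\n")
})

#' EffectMap: per-edge generative coefficients
#'
#' The generative analogue of the per-edge regression model: each edge e has
#' a baseline mean mu_e (Fisher-z units), a sex coefficient b_sex_e (z-units,
#' positive = male > female), an age coefficient b_age_e (z-units per year),
#' an interaction coefficient b_int_e (z-units per year) and a residual s.d.
#' sigma_e > 0. The sets of truly non-null edges per term are recorded so
#' recovery can be scored.
#'
#' @slot edges data.frame with columns `edge_id`, `mu`, `b_sex`, `b_age`,
#'   `b_int`, `sigma` (edge_id is 0-based, matching the edge index tables).
#' @slot nonnull named list of integer vectors of 0-based edge ids for terms
#'   `sex`, `age`, `int`.
#' @slot seed integer seed used to draw the baselines.
#' @export
setClass("EffectMap",
  slots = c(edges = "data.frame", nonnull = "list", seed = "integer"))

setValidity("EffectMap", function(object) {
  e <- object@edges
  msgs <- character()
  need <- c("edge_id", "mu", "b_sex", "b_age", "b_int", "sigma")
  if (!all(need %in% names(e))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (any(e$sigma <= 0)) msgs <- c(msgs, "sigma must be > 0 for all edges")
  nn <- object@nonnull
  if (!all(c("sex", "age", "int") %in% names(nn))) {
    msgs <- c(msgs, "nonnull must list sex, age and int edge sets")
  } else {
    ids <- unlist(nn, use.names = FALSE)
    if (anyDuplicated(ids)) {
      msgs <- c(msgs, "nonnull edge sets must be disjoint")
    }
    if (length(ids) && !all(ids %in% e$edge_id)) {
      msgs <- c(msgs, "nonnull edge ids must belong to the edge index set")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn EffectMap Number of edges covered by the map.
#' @export
nEdges <- function(effects) nrow(effects@edges)

#' @describeIn EffectMap Per-edge coefficient table.
#' @param effects An `EffectMap`.
#' @export
effectTable <- function(effects) effects@edges

#' @describeIn EffectMap Named list of truly non-null edge ids per term.
#' @export
nonnullEdges <- function(effects) effects@nonnull

setMethod("show", "EffectMap", function(object) {
  nn <- vapply(object@nonnull, length, integer(1))
  cat("EffectMap over", nrow(object@edges), "edges\n")
  cat(sprintf("  non-null: sex=%d age=%d int=%d\n",
              nn[["sex"]], nn[["age"]], nn[["int"]]))
  cat(sprintf("  sigma range: [%.3g, %.3g]\n",
              min(object@edges$sigma), max(object@edges$sigma)))
})
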