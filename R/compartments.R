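# Canonical subcellular-compartment vocabulary and label canonicalization.

#' @keywords internal
.IIS_LABELS <- c(
  "extracellular", "cell wall", "plasma membrane", "mitochondrion",
  "endoplasmic reticulum", "golgi apparatus", "endosome", "centrosome",
  "microtubule organizing center", "lysosome", "vacuole", "glyoxysome",
  "glycosome", "peroxisome", "amyloplast", "apicoplast", "chloroplast",
  "plastid", "cytoplasm", "cytosol", "nucleus"
)

# InnateDB exports annotate only five compartments; they fold into the
# canonical vocabulary ("cell surface" is the plasma membrane seen from
# outside; "extracellular region" is the long GO form of "extracellular").
.ALIASES <- c(
  "cell surface"         = "plasma membrane",
  "extracellular region" = "extracellular",
  "extracellular space"  = "extracellular"
)

#' Compartment registry
#'
#' Returns the canonical compartment vocabulary together with the geometric
#' region kind each label maps to in the cell diagram. The vocabulary holds
#' exactly the 21 labels used by IIS-style annotation; the 5 labels used by
#' InnateDB map onto it via aliases (see [canonical_label()]).
#'
#' Region kinds:
#' \describe{
#'   \item{annulus}{cell wall and plasma membrane: a ring between two
#'     concentric circles.}
#'   \item{cytosol_free_region}{cytosol and cytoplasm: inside the cytoplasm
#'     disc but outside the nucleus and every organelle circle.}
#'   \item{extracellular_region}{outside the outermost ring, inside the
#'     canvas.}
#'   \item{organelle_disc}{every other label, including the nucleus, drawn
#'     as a single circle.}
#' }
#'
#' @return A data.frame with columns `label` and `region_kind`.
#' @export
#' @examples
#' reg <- compartment_registry()
#' nrow(reg)  # 21
compartment_registry <- function() {
  kind <- rep("organelle_disc", length(.IIS_LABELS))
  kind[.IIS_LABELS %in% c("cell wall", "plasma membrane")] <- "annulus"
  kind[.IIS_LABELS %in% c("cytoplasm", "cytosol")] <- "cytosol_free_region"
  kind[.IIS_LABELS == "extracellular"] <- "extracellular_region"
  data.frame(label = .IIS_LABELS, region_kind = kind, stringsAsFactors = FALSE)
}

#' Canonicalize a compartment label
#'
#' Case-insensitive match against the canonical vocabulary, applying the
#' InnateDB aliases. Unrecognized labels return `NA`.
#'
#' @param label character vector of raw labels.
#' @return character vector of canonical labels or `NA` where unrecognized.
#' @export
canonical_label <- function(label) {
  x <- tolower(trimws(as.character(label)))
  x[is.na(x)] <- ""
  ali <- .ALIASES[x]
  x[!is.na(ali)] <- ali[!is.na(ali)]
  x[!(x %in% .IIS_LABELS)] <- NA_character_
  x
}

#' Assign a node to its placement compartment
#'
#' Returns the canonical compartment used to place each node: the node's
#' single-valued compartment annotation if it is recognized, otherwise the
#' cytosol. An empty or missing annotation also falls back to the cytosol,
#' so assignment is a total function.
#'
#' @param selected_cc character vector of raw single-valued compartment
#'   annotations (one per node); may contain empty strings or `NA`.
#' @return character vector of canonical labels, never `NA`.
#' @export
#' @examples
#' assign_compartment(c("Mitochondrion", "", "ribosome"))
assign_compartment <- function(selected_cc) {
  out <- canonical_label(selected_cc)
  out[is.na(out)] <- "cytosol"
  out
}

#' Region kind of a canonical label
#' @keywords internal
region_kind_of <- function(label) {
  reg <- compartment_registry()
  kind <- reg$region_kind[match(label, reg$label)]
  if (anyNA(kind)) {
    stop("unknown compartment label(s): ",
         paste(unique(label[is.na(kind)]), collapse = ", "))
  }
  kind
}
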