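#' Marker panel definition
#'
#' A marker panel maps each molecular marker to a functional compartment of
#' the cortical microcircuit (GABAergic interneurons, glutamatergic synapse,
#' astroglia) and to the assay it was quantified with (protein immunoblot or
#' RNA qPCR).
#'
#' @param markers character vector of marker identifiers.
#' @param compartment character vector, one of `"GABAergic"`, `"synaptic"`,
#'   `"astroglial"` per marker.
#' @param assay character vector, one of `"protein"`, `"RNA"` per marker.
#'
#' @return An object of class `marker_panel`: a data.frame with columns
#'   `marker`, `compartment`, `assay`.
#' @seealso [default_panel()] for the 11-marker prefrontal-cortex panel.
#' @export
#' @examples
#' marker_panel(c("A", "B"), c("synaptic", "astroglial"), c("protein", "RNA"))
marker_panel <- function(markers, compartment, assay) {
  markers <- as.character(markers)
  if (anyDuplicated(markers))
    stop("duplicate marker identifiers in panel")
  if (length(compartment) != length(markers) || length(assay) != length(markers))
    stop("'compartment' and 'assay' must have one entry per marker")
  compartment <- match.arg(as.character(compartment),
                           c("GABAergic", "synaptic", "astroglial"),
                           several.ok = TRUE)
  if (length(compartment) != length(markers))
    stop("every marker needs exactly one compartment")
  assay <- match.arg(as.character(assay), c("protein", "RNA"),
                     several.ok = TRUE)
  if (length(assay) != length(markers))
    stop("every marker needs exactly one assay")
  structure(
    data.frame(marker = markers, compartment = compartment, assay = assay,
               stringsAsFactors = FALSE),
    class = c("marker_panel", "data.frame")
  )
}

#' The default 11-marker prefrontal-cortex panel
#'
#' Eight proteins quantified by Western blot (GFAP, GS, GLT1, VGLUT1, SYN1,
#' PSD95, GPHN, GAD67) and three transcripts quantified by qPCR (SST, PV,
#' VIP), partitioned into three compartments:
#' GABAergic = GAD67, SST, PV, VIP; synaptic = VGLUT1, PSD95, SYN1, GPHN;
#' astroglial = GLT1, GFAP, GS.
#'
#' @return A [marker_panel] with 11 rows.
#' @export
#' @examples
#' p <- default_panel()
#' table(p$compartment)
default_panel <- function() {
  marker_panel(
    markers = c("GAD67", "SST", "PV", "VIP",
                "VGLUT1", "PSD95", "SYN1", "GPHN",
                "GLT1", "GFAP", "GS"),
    compartment = c(rep("GABAergic", 4), rep("synaptic", 4),
                    rep("astroglial", 3)),
    assay = c("protein", "RNA", "RNA", "RNA",
              rep("protein", 4), rep("protein", 3))
  )
}

#' Markers belonging to one compartment
#'
#' @param panel a [marker_panel].
#' @param compartment compartment name.
#' @return character vector of marker identifiers.
#' @export
compartment_markers <- function(panel, compartment) {
  stopifnot(inherits(panel, "marker_panel"))
  compartment <- match.arg(compartment,
                           c("GABAergic", "synaptic", "astroglial"))
  panel$marker[panel$compartment == compartment]
}

#' Read / write a panel definition as YAML
#'
#' The YAML file maps each marker to a `compartment:` and `assay:` entry.
#'
#' @param path file path.
#' @param panel a [marker_panel].
#' @return `read_panel_yaml` returns a [marker_panel]; `write_panel_yaml`
#'   returns `path` invisibly.
#' @export
read_panel_yaml <- function(path) {
  def <- yaml::read_yaml(path)
  marker_panel(names(def),
               vapply(def, function(x) x$compartment, character(1)),
               vapply(def, function(x) x$assay, character(1)))
}

#' @rdname read_panel_yaml
#' @export
write_panel_yaml <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  def <- lapply(seq_len(nrow(panel)), function(i)
    list(compartment = panel$compartment[i], assay = panel$assay[i]))
  names(def) <- panel$marker
  yaml::write_yaml(def, path)
  invisible(path)
}

#' Canonical group and sex labels
#'
#' The six stress-duration group labels (in increasing duration) and the
#' two sex labels used throughout the package.
#'
#' @return character vector of labels.
#' @export
#' @examples
#' crs_groups()
crs_groups <- function() c("CRS0", "CRS7", "CRS14", "CRS21", "CRS28", "CRS35")

#' @rdname crs_groups
#' @export
crs_sexes <- function() c("M", "F")
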