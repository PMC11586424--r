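#' Marker panel and cell-type vocabulary
#'
#' A `tme_panel` declares the marker channels measured on a tissue section,
#' the cell-type vocabulary those markers resolve, and a signature matrix of
#' expected expression (rows = types, columns = markers) used by
#' [assign_lineage()]. Types may share a lineage that is split after lineage
#' assignment by thresholding one marker (the PD-L1 split for macrophages and
#' tumor cells).
#'
#' @param markers character vector of marker names (ordered).
#' @param types character vector of cell-type names (ordered).
#' @param signature numeric matrix, `length(types)` x `length(markers)`, of
#'   expected expression (any non-negative scale; rows must be distinct).
#' @param lineages named character vector mapping each type to its lineage
#'   label; defaults to the type names themselves (no shared lineages).
#' @param split optional list describing a post-lineage marker split:
#'   `list(marker=, z_threshold=, positive=, negative=)` where `positive` and
#'   `negative` are named character vectors mapping a lineage to the type it
#'   becomes above / below the z-score threshold.
#' @param priority character vector of types in tie-break order (earlier wins
#'   when assignment scores tie exactly); defaults to `types`.
#' @param tumor_types character vector naming the tumor types of the panel
#'   (used to pick the non-tumor pairs for interaction features).
#' @param proliferation optional list `list(marker=, z_threshold=)` declaring
#'   a proliferation flag (Ki67) orthogonal to lineage.
#' @return An object of class `tme_panel`.
#' @seealso [panel_pdac7()], [panel_tme16()]
#' @export
tme_panel <- function(markers, types, signature, lineages = NULL,
                      split = NULL, priority = types,
                      tumor_types = character(), proliferation = NULL) {
  markers <- as.character(markers)
  types <- as.character(types)
  if (anyDuplicated(markers)) stop("duplicate marker names")
  if (anyDuplicated(types)) stop("duplicate type names")
  signature <- as.matrix(signature)
  if (!identical(dim(signature), c(length(types), length(markers))))
    stop("signature must be a types x markers matrix")
  dimnames(signature) <- list(types, markers)
  if (anyDuplicated(apply(signature, 1L, paste, collapse = "\r")))
    stop("signature rows must be distinct")
  if (is.null(lineages)) lineages <- stats::setNames(types, types)
  if (!setequal(names(lineages), types)) stop("lineages must be named by type")
  lineages <- lineages[types]
  if (!is.null(split)) {
    stopifnot(is.list(split), split$marker %in% markers,
              all(split$positive %in% types), all(split$negative %in% types),
              identical(names(split$positive), names(split$negative)))
    if (is.null(split$z_threshold)) split$z_threshold <- 0.5
  }
  if (!setequal(priority, types)) stop("priority must order all panel types")
  if (!all(tumor_types %in% types)) stop("tumor_types must be panel types")
  structure(list(markers = markers, types = types, signature = signature,
                 lineages = lineages, split = split, priority = priority,
                 tumor_types = tumor_types, proliferation = proliferation),
            class = "tme_panel")
}

#' @export
print.tme_panel <- function(x, ...) {
  cat("tme_panel:", length(x$types), "cell types,",
      length(x$markers), "markers\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  types:  ", paste(x$types, collapse = ", "), "\n")
  if (!is.null(x$split))
    cat("  split:  ", x$split$marker, "z >", x$split$z_threshold, "on",
        paste(names(x$split$positive), collapse = ", "), "\n")
  invisible(x)
}

#' Default 7-type pancreatic TME panel
#'
#' Seven markers (CD4, CD8, CD20, CD11c, CD68, PD-L1, panCK) resolving seven
#' cell types: T helper (Th), cytotoxic T lymphocyte (CTL), B cell, dendritic
#' cell (DC), PD-L1+ and PD-L1- macrophages, and tumor. Macrophages share the
#' "M" lineage and are split on the PD-L1 z-score after lineage assignment.
#'
#' @return A `tme_panel`.
#' @export
panel_pdac7 <- function() {
  markers <- c("CD4", "CD8", "CD20", "CD11c", "CD68", "PDL1", "panCK")
  types <- c("Tumor", "Th", "CTL", "DC", "PDL1pos_M", "PDL1neg_M", "B")
  sig <- matrix(0, length(types), length(markers),
                dimnames = list(types, markers))
  sig["Tumor", "panCK"] <- 2
  sig["Th", "CD4"] <- 2
  sig["CTL", "CD8"] <- 2
  sig["DC", "CD11c"] <- 2
  sig["PDL1pos_M", c("CD68", "PDL1")] <- 2
  sig["PDL1neg_M", "CD68"] <- 2
  sig["B", "CD20"] <- 2
  lin <- stats::setNames(types, types)
  lin[c("PDL1pos_M", "PDL1neg_M")] <- "M"
  tme_panel(markers, types, sig, lineages = lin,
            split = list(marker = "PDL1", z_threshold = 0.5,
                         positive = c(M = "PDL1pos_M"),
                         negative = c(M = "PDL1neg_M")),
            priority = types, tumor_types = "Tumor")
}

#' Extended 16-type TME panel
#'
#' Seventeen markers resolving sixteen cell types including lymphoid (Th, CTL,
#' Treg, B, plasma), myeloid (M1, M2, DC, neutrophil, monocyte), mesenchymal
#' (endothelial, fibroblast, FAP+ fibroblast) and PD-L1 split tumor cells,
#' plus an all-low "Other" class. Ki67 is declared as a proliferation flag
#' orthogonal to lineage.
#'
#' @return A `tme_panel`.
#' @export
panel_tme16 <- function() {
  markers <- c("CD3", "CD4", "CD8", "Foxp3", "CD20", "CD38", "CD68", "CD163",
               "CD11c", "CD14", "MPO", "CD31", "FAP", "aSMA", "panCK",
               "PDL1", "Ki67")
  types <- c("PDL1pos_TC", "PDL1neg_TC", "Th", "CTL", "Treg", "B", "Plasma",
             "M1", "M2", "DC", "Neutrophil", "Monocyte", "Endothelial",
             "Fibroblast", "FAPpos_Fb", "Other")
  sig <- matrix(0, length(types), length(markers),
                dimnames = list(types, markers))
  sig["PDL1pos_TC", c("panCK", "PDL1")] <- 2
  sig["PDL1neg_TC", "panCK"] <- 2
  sig["Th", c("CD3", "CD4")] <- 2
  sig["CTL", c("CD3", "CD8")] <- 2
  sig["Treg", c("CD3", "CD4", "Foxp3")] <- 2
  sig["B", "CD20"] <- 2
  sig["Plasma", "CD38"] <- 2
  sig["M1", "CD68"] <- 2
  sig["M2", c("CD68", "CD163")] <- 2
  sig["DC", "CD11c"] <- 2
  sig["Neutrophil", "MPO"] <- 2
  sig["Monocyte", "CD14"] <- 2
  sig["Endothelial", "CD31"] <- 2
  sig["Fibroblast", "aSMA"] <- 2
  sig["FAPpos_Fb", c("FAP", "aSMA")] <- 2
  lin <- stats::setNames(types, types)
  lin[c("PDL1pos_TC", "PDL1neg_TC")] <- "TC"
  # priority: tumor > T subsets > myeloid > B/plasma > mesenchymal > other
  prio <- c("PDL1pos_TC", "PDL1neg_TC", "Treg", "Th", "CTL",
            "M2", "M1", "DC", "Neutrophil", "Monocyte",
            "B", "Plasma", "Endothelial", "FAPpos_Fb", "Fibroblast", "Other")
  tme_panel(markers, types, sig, lineages = lin,
            split = list(marker = "PDL1", z_threshold = 0.5,
                         positive = c(TC = "PDL1pos_TC"),
                         negative = c(TC = "PDL1neg_TC")),
            priority = prio, tumor_types = c("PDL1pos_TC", "PDL1neg_TC"),
            proliferation = list(marker = "Ki67", z_threshold = 1))
}
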