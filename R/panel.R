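#' Antibody panel definition
#'
#' A panel maps acquisition channels to marker names and records which
#' markers are excluded from downstream analysis (e.g. for batch variation).
#'
#' @param entries data.frame with columns `channel_id`, `marker`, `category`
#'   (one of `"surface"`, `"intracellular"`, `"light_chain"`, `"viability"`,
#'   `"ignore"`).
#' @param exclusion_list character vector of marker names to drop before
#'   clustering/differential analysis (a subset of `entries$marker`).
#' @return An object of class `panel_definition`.
#' @export
panel_definition <- function(entries, exclusion_list = character()) {
  stopifnot(is.data.frame(entries),
            all(c("channel_id", "marker", "category") %in% names(entries)))
  cats <- c("surface", "intracellular", "light_chain", "viability", "ignore")
  if (!all(entries$category %in% cats)) {
    stop("unknown category; allowed: ", paste(cats, collapse = ", "))
  }
  live <- entries[entries$category != "ignore", , drop = FALSE]
  if (anyDuplicated(live$marker)) {
    stop("marker names must be unique: ",
         paste(unique(live$marker[duplicated(live$marker)]), collapse = ", "))
  }
  if (anyDuplicated(entries$channel_id)) stop("channel ids must be unique")
  if (!all(exclusion_list %in% live$marker)) {
    stop("exclusion_list must be a subset of panel markers; unknown: ",
         paste(setdiff(exclusion_list, live$marker), collapse = ", "))
  }
  structure(list(entries = entries,
                 exclusion_list = unique(exclusion_list)),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  live <- panel_markers(x)
  cat("panel_definition:", length(live), "markers (",
      nrow(x$entries), "channels ),",
      length(x$exclusion_list), "batch-excluded\n")
  invisible(x)
}

#' Markers of a panel (non-ignore channels, panel order)
#' @param panel a `panel_definition`.
#' @param analysis_only drop the batch exclusion list as well?
#' @return character vector of marker names.
#' @export
panel_markers <- function(panel, analysis_only = FALSE) {
  m <- panel$entries$marker[panel$entries$category != "ignore"]
  if (analysis_only) m <- setdiff(m, panel$exclusion_list)
  m
}

#' Default 37-channel myeloma CyTOF panel
#'
#' The full designed panel: 7 phosphoproteins, 6 transcription factors
#' (including SOX2), 2 survival proteins, CRBN, cleaved caspase-3, Ki-67,
#' 17 surface markers (including CD27 and CD147) and the two immunoglobulin
#' light chains. SOX2, CD27 and CD147 ship on the batch exclusion list,
#' leaving the 34 analysis markers.
#'
#' @return A `panel_definition` with 37 entries and a 3-marker exclusion list.
#' @export
default_panel <- function() {
  phospho <- c("pAKT", "pCREB", "pERK", "pp38", "pRB", "pS6", "pSTAT3")
  tf <- c("MYC", "IkBa", "IKZF1", "IKZF3", "IRF4", "SOX2")
  intra_other <- c("BCL-2", "MCL-1", "CRBN", "clCasp3", "Ki-67")
  surface <- c("CD117", "CD138", "CD16", "CD19", "CD20", "CD28", "CD3",
               "CD34", "CD38", "CD45", "CD56", "CD81", "CD71", "CD49d",
               "CD274", "CD27", "CD147")
  lc <- c("kappa", "lambda")
  markers <- c(phospho, tf, intra_other, surface, lc)
  category <- c(rep("intracellular", length(phospho) + length(tf) +
                      length(intra_other)),
                rep("surface", length(surface)),
                rep("light_chain", 2L))
  entries <- data.frame(
    channel_id = sprintf("ch%02d", seq_along(markers)),
    marker = markers,
    category = category,
    stringsAsFactors = FALSE
  )
  panel_definition(entries, exclusion_list = c("SOX2", "CD27", "CD147"))
}
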