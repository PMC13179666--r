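# The 122-region parcellation: 8 thalamic subdivision nodes (4 anatomical
# nuclei groups x 2 hemispheres, from a THOMAS-style segmentation collapsed
# to anterior / lateral / medial / pulvinar) plus 114 cortical, subcortical
# and cerebellar regions in a Harvard-Oxford-style naming scheme.

the <- new.env(parent = emptyenv())

#' Region atlas for the 122-node connectivity analysis
#'
#' Returns the packaged atlas: one row per region with columns `region`
#' (unique label), `base` (label without hemisphere suffix), `hemisphere`
#' (`L`, `R`, or `M` for midline), `class` (`thalamic_subdivision` or
#' `other`), `subdivision` (`anterior`, `lateral`, `medial`, `pulvinar`;
#' `NA` for non-thalamic regions), and `lobe` (coarse community tag used by
#' the synthetic mean-connectivity model).
#'
#' @return A `data.frame` with 122 rows.
#' @export
#' @examples
#' atlas <- thalamus_atlas()
#' table(atlas$class)
thalamus_atlas <- function() {
  if (is.null(the$atlas)) {
    path <- system.file("extdata", "atlas_122.tsv", package = "thalnet",
                        mustWork = TRUE)
    atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(nrow(atlas) == 122, !anyDuplicated(atlas$region))
    the$atlas <- atlas
  }
  the$atlas
}

# THOMAS nucleus label -> analysis subdivision.
.thomas_map <- c(
  AV = "anterior",
  VA = "lateral", VLa = "lateral", VLP = "lateral", VPL = "lateral",
  CM = "medial", `MD-Pf` = "medial",
  Pul = "pulvinar"
)

#' Map THOMAS thalamic nucleus labels to analysis subdivisions
#'
#' The four subdivisions group the THOMAS nuclei as: anterior =
#' anteroventral (AV); lateral = ventral anterior (VA), ventral lateral
#' anterior (VLa), ventral lateral posterior (VLP), ventral posterolateral
#' (VPL); medial = centromedian (CM), mediodorsal (MD-Pf); pulvinar = Pul.
#'
#' @param nucleus Character vector of THOMAS nucleus labels.
#' @return Character vector of subdivisions.
#' @export
#' @examples
#' map_thomas_to_subdivisions(c("AV", "VPL", "CM"))
map_thomas_to_subdivisions <- function(nucleus) {
  out <- .thomas_map[nucleus]
  if (anyNA(out)) {
    bad <- unique(nucleus[is.na(out)])
    stopf("unknown THOMAS nucleus label(s): %s (known: %s)",
          paste(bad, collapse = ", "), paste(names(.thomas_map), collapse = ", "))
  }
  unname(out)
}

#' Label of a thalamic subdivision node
#'
#' @param subdivision One of `"anterior"`, `"lateral"`, `"medial"`,
#'   `"pulvinar"`.
#' @param side `"L"` or `"R"`.
#' @param atlas Atlas data frame (default the packaged atlas).
#' @return The region label, e.g. `"Thal_Pulvinar_L"`.
#' @export
thalamic_region <- function(subdivision, side, atlas = thalamus_atlas()) {
  subdivision <- match.arg(subdivision,
                           c("anterior", "lateral", "medial", "pulvinar"))
  side <- match.arg(side, c("L", "R"))
  hit <- atlas$region[atlas$class == "thalamic_subdivision" &
                        atlas$subdivision == subdivision &
                        atlas$hemisphere == side]
  if (length(hit) != 1L) stopf("no unique region for %s/%s", subdivision, side)
  hit
}

# Mirror a region label across the midline (L <-> R, midline unchanged).
mirror_region <- function(region, atlas = thalamus_atlas()) {
  i <- match(region, atlas$region)
  if (anyNA(i)) stopf("unknown region label(s): %s",
                      paste(region[is.na(i)], collapse = ", "))
  hemi <- atlas$hemisphere[i]
  flip <- ifelse(hemi == "L", "R", ifelse(hemi == "R", "L", "M"))
  out <- ifelse(hemi == "M", atlas$region[i],
                paste(atlas$base[i], flip, sep = "_"))
  out
}

#' Mirror a connectivity matrix across the midline
#'
#' Swaps left and right homologues of every region (midline regions map to
#' themselves), so that a right-focus subject's matrix can be expressed in
#' a focus-on-the-left frame (or vice versa) before ipsi/contra pooling.
#'
#' @param mat Symmetric connectivity matrix with atlas region dimnames.
#' @param atlas Atlas data frame.
#' @return The mirrored matrix, same dimnames order as the input.
#' @export
mirror_matrix <- function(mat, atlas = thalamus_atlas()) {
  labs <- rownames(mat)
  perm <- match(mirror_region(labs, atlas), labs)
  out <- mat[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(mat)
  out
}
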