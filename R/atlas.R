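#' White-matter tract names in the style of the JHU ICBM-DTI-81 atlas
#'
#' The standard 48-region white-matter label list (5 commissural/brainstem
#' singletons, the fornix body, and 21 bilateral pairs). Only the cardinality
#' and naming of the atlas are mirrored here; the synthetic atlas geometry
#' (see [makeAtlasLabels]) makes no attempt to mimic real tract shapes.
#'
#' @param abbreviated if `TRUE`, return short codes suitable for column
#'   names (e.g. "ALIC_R"); otherwise full anatomical names.
#' @return character vector of length 48.
#' @export
jhuTractNames <- function(abbreviated = FALSE) {
  singles <- c("Middle cerebellar peduncle" = "MCP",
               "Pontine crossing tract" = "PCT",
               "Genu of corpus callosum" = "GCC",
               "Body of corpus callosum" = "BCC",
               "Splenium of corpus callosum" = "SCC",
               "Fornix (column and body)" = "FX")
  pairs <- c("Corticospinal tract" = "CST",
             "Medial lemniscus" = "ML",
             "Inferior cerebellar peduncle" = "ICP",
             "Superior cerebellar peduncle" = "SCP",
             "Cerebral peduncle" = "CP",
             "Anterior limb of internal capsule" = "ALIC",
             "Posterior limb of internal capsule" = "PLIC",
             "Retrolenticular part of internal capsule" = "RLIC",
             "Anterior corona radiata" = "ACR",
             "Superior corona radiata" = "SCR",
             "Posterior corona radiata" = "PCR",
             "Posterior thalamic radiation" = "PTR",
             "Sagittal stratum" = "SS",
             "External capsule" = "EC",
             "Cingulum (cingulate gyrus)" = "CGC",
             "Cingulum (hippocampus)" = "CGH",
             "Fornix (cres) / Stria terminalis" = "FXST",
             "Superior longitudinal fasciculus" = "SLF",
             "Superior fronto-occipital fasciculus" = "SFO",
             "Uncinate fasciculus" = "UNC",
             "Tapetum" = "TAP")
  full <- c(names(singles),
            as.vector(rbind(paste(names(pairs), "R"), paste(names(pairs), "L"))))
  abbr <- c(unname(singles),
            as.vector(rbind(paste0(pairs, "_R"), paste0(pairs, "_L"))))
  if (abbreviated) abbr else full
}

# Factor n into three integers a*b*c == n with factors as balanced as
# possible (used to tile the grid into labelled blocks).
balancedTriple <- function(n) {
  best <- NULL
  for (a in seq_len(n)) {
    if (n %% a) next
    m <- n %/% a
    for (b in seq_len(m)) {
      if (m %% b) next
      cc <- m %/% b
      tr <- sort(c(a, b, cc))
      score <- tr[3] / tr[1]
      if (is.null(best) || score < best$score)
        best <- list(triple = tr, score = score)
    }
  }
  best$triple
}

#' Synthetic label atlas and analysis mask
#'
#' Tiles the grid into `nRois` disjoint rectangular regions (a stand-in for
#' a white-matter label atlas: correct region count and name list, no
#' anatomical geometry). Labels are assigned to blocks in seeded random
#' order. The accompanying binary mask is the union of all regions and acts
#' as the analysis (skeleton stand-in) mask.
#'
#' @param nRois number of regions (default 48, the JHU-style tract count).
#' @param gridShape integer length-3 grid size.
#' @param seed RNG seed for the label-to-block assignment.
#' @param minVoxels smallest admissible region size in voxels.
#' @param spacing voxel size in mm per axis.
#' @param names region names; defaults to [jhuTractNames] codes when
#'   `nRois` is 48, else "ROI01"...
#' @return a list with elements `labels` (3D integer array, 0 = background),
#'   `names` (length `nRois`), `mask` (3D logical), `spacing`.
#' @examples
#' atl <- makeAtlasLabels(48, c(24, 24, 12), seed = 1)
#' length(unique(atl$labels[atl$labels > 0]))
#' @export
makeAtlasLabels <- function(nRois = 48, gridShape = c(24, 24, 12), seed = NULL,
                            minVoxels = 8, spacing = c(2, 2, 2),
                            names = NULL) {
  nRois <- as.integer(nRois)
  gridShape <- as.integer(gridShape)
  stopifnot(nRois >= 1, length(gridShape) == 3L)
  tr <- balancedTriple(nRois)
  # match the largest block-count to the largest grid axis
  tr <- tr[order(order(gridShape))]
  if (any(gridShape < tr))
    stop("grid too small for the requested number of regions")
  if (prod(gridShape) < nRois * minVoxels)
    stop("grid too small for ", nRois, " regions of >= ", minVoxels, " voxels")
  cuts <- lapply(1:3, function(ax) {
    if (tr[ax] == 1L) rep(1L, gridShape[ax])
    else as.integer(cut(seq_len(gridShape[ax]), breaks = tr[ax],
                        labels = FALSE))
  })
  block <- array(0L, gridShape)
  blockId <- function(i, j, k) (k - 1L) * tr[1] * tr[2] + (j - 1L) * tr[1] + i
  block[] <- blockId(cuts[[1]][slice.index(block, 1)],
                     cuts[[2]][slice.index(block, 2)],
                     cuts[[3]][slice.index(block, 3)])
  perm <- withSeed(seed, sample.int(nRois))
  labels <- array(perm[block], gridShape)
  storage.mode(labels) <- "integer"
  counts <- tabulate(labels, nRois)
  if (any(counts < minVoxels))
    stop("grid too small: a region would have fewer than ", minVoxels,
         " voxels")
  if (is.null(names)) {
    names <- if (nRois == 48L) jhuTractNames(abbreviated = TRUE)
             else sprintf("ROI%02d", seq_len(nRois))
  }
  stopifnot(length(names) == nRois)
  list(labels = labels, names = names, mask = labels > 0L,
       spacing = as.numeric(spacing))
}
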