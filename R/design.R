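# Experimental design: ligand x time x replicate layout with a single
# untreated control collected at time 0 (CTRL_0), mirroring a 48-hour
# ligand-perturbation time course run in replicate collections.

#' Construct a design specification
#'
#' @param ligands character vector of treatment labels (the untreated control
#'   `CTRL` is implicit and collected only at time 0; do not list it).
#' @param times numeric vector of collection times in hours; must include 0.
#' @param replicates integer, biological replicates per condition (>= 1).
#' @param collections integer, number of experimental collections; replicates
#'   are assigned to collections round-robin.
#' @param seed integer root seed recorded with the design.
#' @return A `design_spec` list.
#' @export
design_spec <- function(ligands = c("PBS", "EGF", "HGF", "OSM",
                                    "BMP2_EGF", "IFNG_EGF", "TGFB_EGF"),
                        times = c(0, 1, 4, 8, 24, 48),
                        replicates = 3, collections = 1, seed = 1L) {
  if (anyDuplicated(ligands)) stop("duplicate condition labels in `ligands`")
  if ("CTRL" %in% ligands) stop("`CTRL` is implicit; do not list it as a treatment")
  if (!0 %in% times) stop("`times` must include 0 (the CTRL collection time)")
  if (anyDuplicated(times)) stop("duplicate time points")
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (collections < 1) stop("`collections` must be >= 1")
  structure(list(ligands = ligands, times = sort(times),
                 replicates = as.integer(replicates),
                 collections = as.integer(collections),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate the sample-metadata table for a design
#'
#' One row per (ligand, time > 0, replicate) plus the CTRL samples at time 0.
#' Deterministic given the spec (the layout itself involves no randomness).
#'
#' @param spec a [design_spec()].
#' @return A data.frame with columns `sample_id`, `ligand`, `time`,
#'   `replicate`, `collection`.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  post <- spec$times[spec$times > 0]
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      time = post, ligand = spec$ligands,
                      stringsAsFactors = FALSE)
  ctrl <- data.frame(replicate = seq_len(spec$replicates), time = 0,
                     ligand = "CTRL", stringsAsFactors = FALSE)
  meta <- rbind(ctrl, grid)[, c("ligand", "time", "replicate")]
  meta$collection <- ((meta$replicate - 1L) %% spec$collections) + 1L
  meta$sample_id <- sprintf("%s_%g_R%d", meta$ligand, meta$time, meta$replicate)
  rownames(meta) <- NULL
  meta[, c("sample_id", "ligand", "time", "replicate", "collection")]
}
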