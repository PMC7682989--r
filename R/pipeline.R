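## Orchestration: run the full metric set over a list of states and emit a
## per-(entry, protomer) summary table with provenance.

#' Load a run configuration
#'
#' YAML with: `entries` (list of `label`, `structure`, optional `map`),
#' `alpha2_reference` and `area_reference` (labels among the entries;
#' typically the occluded apo state for rotation angles and the
#' substrate-bound state for interface-area changes), optional `partition`
#' (path; packaged default when absent), optional `options` (`probe`,
#' `n_points`, `threshold_sigma`, `protein_mask_radius`,
#' `slab_half_width`, `deformation_radius`), optional `seed` and
#' `output_dir`.
#'
#' @param path YAML config file.
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entries) || !length(cfg$entries))
    stop("run config lists no entries")
  labels <- vapply(cfg$entries, function(e) as.character(e$label),
                   character(1))
  if (anyDuplicated(labels)) stop("duplicate entry labels in run config")
  for (ref in c("alpha2_reference", "area_reference"))
    if (!is.null(cfg[[ref]]) && !cfg[[ref]] %in% labels)
      stop(ref, " '", cfg[[ref]], "' is not among the entry labels")
  defaults <- list(probe = 1.4, n_points = 960, threshold_sigma = 1,
                   protein_mask_radius = 4, slab_half_width = 25,
                   deformation_radius = 15)
  cfg$options <- utils::modifyList(defaults,
                                   if (is.null(cfg$options)) list()
                                   else cfg$options)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "run_config"
  cfg
}

analyze_one_entry <- function(entry, partition, refs, opts) {
  model <- read_structure(entry$structure, entry_id = entry$label)
  dens <- if (!is.null(entry$map) && nzchar(entry$map))
    read_density(entry$map) else NULL
  rows <- list()
  for (chain in model$protomer_chains) {
    frame <- tryCatch(membrane_frame(model, partition, chain),
                      error = function(e) NULL)
    if (is.null(frame) && !is.null(refs$frame_donor)) {
      # single-protomer deposition: inherit the frame from the designated
      # trimeric reference after scaffold superposition
      sc <- shared_ca(refs$frame_donor$model, model,
                      partition_set(partition, "scaffold"),
                      refs$frame_donor$chain, chain)
      fit <- kabsch(sc$a, sc$b)
      donor <- refs$frame_donor$frame
      frame <- membrane_frame_from(as.numeric(fit$R %*% donor$normal),
                                   apply_rigid(rbind(donor$center),
                                               fit$R, fit$t)[1, ])
    }
    alpha1 <- if (!is.null(frame))
      transport_tilt(model, partition, chain, frame) else NA_real_
    d_tip <- tryCatch(
      ca_distance(model, partition$reference_residues$r276,
                  partition$reference_residues$p356, chain),
      error = function(e) NA_real_)
    alpha2 <- rmsd_val <- shift_val <- NA_real_
    n_shared <- NA_integer_
    if (!is.null(refs$alpha2)) {
      rb <- rotation_between(refs$alpha2$model, model, partition,
                             refs$alpha2$chain, chain)
      alpha2 <- rb$angle
      n_shared <- rb$n_transport
      rmsd_val <- rmsd_ca(refs$alpha2$model, model, NULL,
                          refs$alpha2$chain, chain)
      if (!is.null(frame))
        shift_val <- com_shift_along_normal(refs$alpha2$model, model,
                                            partition,
                                            frame = refs$alpha2$frame,
                                            chain_a = refs$alpha2$chain,
                                            chain_b = chain)
    }
    iface <- buried_interface_area(model,
                                   partition_set(partition,
                                                 "hp2_tm8a_motif"),
                                   partition_set(partition, "scaffold"),
                                   chain = chain, probe = opts$probe,
                                   n_points = opts$n_points)
    darea <- if (!is.null(refs$area)) iface$area - refs$area else NA_real_
    deform <- NA_real_
    if (!is.null(dens) && !is.null(frame)) {
      deform <- tryCatch({
        seg <- segment_nanodisc(dens, model, frame,
                                threshold_sigma = opts$threshold_sigma,
                                protein_mask_radius =
                                  opts$protein_mask_radius,
                                slab_half_width = opts$slab_half_width)
        surf <- leaflet_surface(seg, frame, side = "cytoplasmic")
        surf <- reference_zero(surf, model,
                               partition$reference_residues$n_terminus_range,
                               chain = chain)
        max_deformation(surf, "near_transport_domain", model = model,
                        reference = partition_set(partition, "transport"),
                        chain = chain, radius = opts$deformation_radius)
      }, error = function(e) NA_real_)
    }
    rows[[length(rows) + 1]] <- data.frame(
      entry_id = entry$label, protomer = chain,
      alpha1_deg = alpha1, alpha2_deg = alpha2,
      d_tip_A = d_tip, rmsd_A = rmsd_val, com_shift_A = shift_val,
      interface_area_A2 = iface$area, delta_area_A2 = darea,
      max_deformation_A = deform, n_shared_ca = n_shared,
      failed = FALSE, reason = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Analyze a set of transporter states
#'
#' Runs the full metric set — transport-domain tilt, rotation and RMSD
#' against the rotation reference, gating distance, translocation shift,
#' HP2/TM8a-scaffold interface area and its change against the area
#' reference, and (when a map is given) the cytoplasmic nanodisc
#' deformation extremum near the transport domain — over every entry and
#' protomer. A failing entry yields rows marked `failed` with the reason;
#' the run continues.
#'
#' @param config a `run_config` (see [load_run_config()]) or path to one.
#' @return data.frame with one row per (entry, protomer), sorted by entry
#'   label then protomer; attribute `manifest` records every parameter
#'   used. When `config$output_dir` is set, `summary.tsv`, `summary.json`
#'   and `manifest.json` are written there.
#' @export
analyze_states <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  partition <- load_partition(config$partition)
  opts <- config$options
  labels <- vapply(config$entries, function(e) as.character(e$label),
                   character(1))
  refs <- list()
  # resolve references first (also used as the frame donor for monomers)
  ref_label <- config$alpha2_reference
  if (!is.null(ref_label)) {
    e <- config$entries[[match(ref_label, labels)]]
    m <- tryCatch(read_structure(e$structure, entry_id = e$label),
                  error = function(err) NULL)
    if (!is.null(m)) {
      ch <- m$protomer_chains[1]
      fr <- tryCatch(membrane_frame(m, partition, ch),
                     error = function(err) NULL)
      refs$alpha2 <- list(model = m, chain = ch, frame = fr)
      if (!is.null(fr))
        refs$frame_donor <- list(model = m, chain = ch, frame = fr)
    }
  }
  if (!is.null(config$area_reference)) {
    e <- config$entries[[match(config$area_reference, labels)]]
    m <- tryCatch(read_structure(e$structure, entry_id = e$label),
                  error = function(err) NULL)
    if (!is.null(m))
      refs$area <- buried_interface_area(
        m, partition_set(partition, "hp2_tm8a_motif"),
        partition_set(partition, "scaffold"),
        chain = m$protomer_chains[1], probe = opts$probe,
        n_points = opts$n_points)$area
  }
  rows <- lapply(config$entries, function(entry) {
    tryCatch(analyze_one_entry(entry, partition, refs, opts),
             error = function(e) data.frame(
               entry_id = entry$label, protomer = NA_character_,
               alpha1_deg = NA_real_, alpha2_deg = NA_real_,
               d_tip_A = NA_real_, rmsd_A = NA_real_,
               com_shift_A = NA_real_, interface_area_A2 = NA_real_,
               delta_area_A2 = NA_real_, max_deformation_A = NA_real_,
               n_shared_ca = NA_integer_, failed = TRUE,
               reason = conditionMessage(e), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$entry_id, out$protomer), , drop = FALSE]
  rownames(out) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("elevatorEM")),
    entries = lapply(config$entries, function(e)
      list(label = e$label, structure = e$structure,
           map = if (is.null(e$map)) NA else e$map)),
    alpha2_reference = config$alpha2_reference,
    area_reference = config$area_reference,
    partition = if (is.null(config$partition)) "packaged default"
                else config$partition,
    options = opts, seed = config$seed)
  attr(out, "manifest") <- manifest
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    num <- vapply(out, is.numeric, logical(1))
    tsv <- out
    tsv[num] <- lapply(tsv[num], function(x) ifelse(is.na(x), NA,
                                                    signif(x, 8)))
    write.table(tsv, file.path(config$output_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out, file.path(config$output_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (any(out$failed))
    warning(sum(out$failed), " entry/entries failed; see the `reason` column")
  out
}
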