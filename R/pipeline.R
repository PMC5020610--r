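# Full-analysis orchestration: run every analysis stage over an input (or
# synthetic preset) ensemble pair, emit the complete table set as TSV with
# a checksum manifest, and difference two completed runs.

#' Configuration for a full analysis run
#'
#' Collects inputs, cutoffs, binning and seeds for [run_full_analysis()].
#' Reaction-coordinate bin edges are fixed (not data-driven) so that runs
#' over different conditions remain comparable bin by bin.
#'
#' @param out_dir Output directory (created if needed).
#' @param input,input_ligand Ensembles ([ensemble()] objects or
#'   multi-MODEL PDB paths) for the ligand-free and ligand-bearing
#'   systems; `input_ligand` (or either) may be `NULL`. When both are
#'   `NULL` the synthetic presets `"hairpin-dimer"` and
#'   `"hairpin-dimer+ligand"` are generated with `preset_frames` frames.
#' @param topology Optional [topology()] or declaration path used when
#'   reading PDB inputs.
#' @param preset_frames Frames per generated preset (default 40).
#' @param temperature_K Analysis temperature (default 310).
#' @param cluster_cutoff Daura RMSD cutoff, nm (default 0.35).
#' @param contact_cutoff Heavy-atom contact cutoff, nm (default 0.5).
#' @param hbond_d,hbond_angle Geometric H-bond criterion (0.35 nm, 30
#'   degrees).
#' @param stacking Thresholds passed to [stacking_classify()].
#' @param rg_breaks,hbond_breaks Fixed bin edges of the free-energy
#'   surface: Rg bin width 0.02 nm, H-bond bins of width 1.
#' @param top_k Clusters reported in the summary (default 6).
#' @param seed Master seed for every stochastic stage.
#' @param ccs_frames,ccs_n_orientations,ccs_n_points CCS stage: number of
#'   top-cluster frames and sampling effort.
#' @return An `"analysis_config"` list.
#' @export
analysis_config <- function(out_dir, input = NULL, input_ligand = NULL,
                            topology = NULL, preset_frames = 40,
                            temperature_K = 310, cluster_cutoff = 0.35,
                            contact_cutoff = 0.5, hbond_d = 0.35,
                            hbond_angle = 30,
                            stacking = list(d_par = 0.55, d_perp = 0.75,
                                            ang_par = 30, ang_perp = 60),
                            rg_breaks = seq(0.5, 4.0, by = 0.02),
                            hbond_breaks = seq(-0.5, 80.5, by = 1),
                            top_k = 6, seed = 1, ccs_frames = 3,
                            ccs_n_orientations = 100, ccs_n_points = 2000) {
  for (v in c(cluster_cutoff, contact_cutoff, hbond_d, hbond_angle)) {
    if (v <= 0) stop("all cutoffs must be > 0")
  }
  structure(list(out_dir = out_dir, input = input,
                 input_ligand = input_ligand, topology = topology,
                 preset_frames = preset_frames,
                 temperature_K = temperature_K,
                 cluster_cutoff = cluster_cutoff,
                 contact_cutoff = contact_cutoff, hbond_d = hbond_d,
                 hbond_angle = hbond_angle, stacking = stacking,
                 rg_breaks = rg_breaks, hbond_breaks = hbond_breaks,
                 top_k = top_k, seed = seed, ccs_frames = ccs_frames,
                 ccs_n_orientations = ccs_n_orientations,
                 ccs_n_points = ccs_n_points),
            class = "analysis_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.cm_table <- function(cm) {
  m <- cm$matrix
  out <- as.data.frame(m)
  names(out) <- paste0("r", cm$col_resid)
  cbind(resid = cm$row_resid, out)
}

#' Run the full paper-style analysis
#'
#' Executes every analysis stage over the configured ensembles and writes
#' the complete table set: per-class and per-residue secondary structure,
#' beta-strand length distribution, Daura clustering with top-cluster
#' summary and center structures, the cluster-1 interface contact map,
#' the (Rg, H-bond number) free-energy surface with basins, inter/intra
#' MC-MC and SC-SC contact maps, ligand-residue contacts, stacking
#' statistics with the (distance, angle) surface, intra-ligand ring
#' torsion distributions, the cation-pi distance distribution, split-half
#' convergence diagnostics, and projection-approximation CCS of
#' top-cluster structures. Ligand-dependent stages are skipped (and
#' logged) for ligand-free inputs. A `manifest.tsv` lists every output
#' with its MD5 checksum; runs are deterministic for fixed seeds, so
#' rerunning a config reproduces the manifest byte for byte.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with per-system output directories and the
#'   manifest tibble.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) stop("config must be an analysis_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  load_input <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "ensemble")) return(x)
    read_multi_model_pdb(x, topology_spec = config$topology)
  }
  ens0 <- load_input(config$input)
  ens1 <- load_input(config$input_ligand)
  if (is.null(ens0) && is.null(ens1)) {
    note("inputs: synthetic presets, n_frames=", config$preset_frames,
         ", seed=", config$seed)
    ens0 <- synth_preset("hairpin-dimer", config$preset_frames,
                         seed = config$seed)$ensemble
    ens1 <- synth_preset("hairpin-dimer+ligand", config$preset_frames,
                         seed = config$seed)$ensemble
  }
  systems <- list()
  if (!is.null(ens0)) systems$without_ligand <- ens0
  if (!is.null(ens1)) systems$with_ligand <- ens1

  manifest <- list()
  for (sys_name in names(systems)) {
    ens <- systems[[sys_name]]
    dir_out <- file.path(config$out_dir, sys_name)
    dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)
    written <- .analyze_system(ens, dir_out, config, note, sys_name)
    manifest[[sys_name]] <- tibble::tibble(
      file = file.path(sys_name, basename(written)),
      md5 = unname(tools::md5sum(written)))
  }
  manifest <- dplyr::bind_rows(manifest)
  .write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 systems = names(systems)))
}

# All stages for one system; returns the written file paths.
.analyze_system <- function(ens, dir_out, config, note, sys_name) {
  out <- character(0)
  emit <- function(x, name) {
    out <<- c(out, .write_tsv(x, file.path(dir_out, name)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for ", sys_name, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  has_ligand <- length(select_atoms(ens$topology, class = "ligand")) > 0
  note(sys_name, ": ", n_frames(ens), " frames, ligand=", has_ligand)

  stage("secondary_structure", {
    assign <- assign_ss(ens)
    prof <- ss_profile(assign)
    emit(prof$summary, "ss_summary.tsv")
    emit(prof$residue, "ss_profile_residue.tsv")
    emit(strand_length_pdf(assign), "strand_length.tsv")
    note(sys_name, ": secondary structure done")
    assign
  }) -> assign

  stage("clustering", {
    M <- rmsd_matrix(ens)
    cl <- daura_cluster(M, cutoff = config$cluster_cutoff)
    k <- min(config$top_k, length(cl$clusters))
    smry <- cluster_summary(cl, ens, k = k,
                            centers_path = file.path(dir_out, "cluster_centers.pdb"))
    out <- c(out, file.path(dir_out, "cluster_centers.pdb"))
    emit(smry, "clusters.tsv")
    emit(tidy(cl), "cluster_assignment.tsv")
    note(sys_name, ": ", length(cl$clusters), " clusters (cutoff ",
         config$cluster_cutoff, " nm)")
    cl
  }) -> cl

  stage("cluster1_interface", {
    c1 <- subset_frames(ens, cl$clusters[[1]]$members)
    emit(.cm_table(contact_probability(c1, "MC-MC", "inter",
                                       config$contact_cutoff)),
         "cluster1_inter_mcmc.tsv")
    emit(ss_profile(assign_ss(c1))$residue, "cluster1_ss_profile.tsv")
  })

  stage("free_energy_surface", {
    rg <- radius_of_gyration(ens)
    hb <- suppressWarnings(hbond_count(ens, config$hbond_d, config$hbond_angle))
    fes <- fes2d(rg, hb, weights = ens$weights, xbreaks = config$rg_breaks,
                 ybreaks = config$hbond_breaks,
                 temperature_K = config$temperature_K)
    emit(tidy(fes), "fes_rg_hbonds.tsv")
    emit(find_basins(fes), "fes_basins.tsv")
    note(sys_name, ": FES over Rg x H-bonds done")
  })

  stage("contact_maps", {
    for (mode in c("MC-MC", "SC-SC")) {
      for (scope in c("inter", "intra")) {
        nm <- paste0("contacts_", scope, "_",
                     if (mode == "MC-MC") "mcmc" else "scsc", ".tsv")
        emit(.cm_table(contact_probability(ens, mode, scope,
                                           config$contact_cutoff)), nm)
      }
    }
  })

  if (has_ligand) {
    stage("ligand_contacts", {
      lc <- ligand_residue_contacts(ens, config$contact_cutoff)
      emit(lc$residue_pooled, "ligand_contacts_residue.tsv")
      emit(lc$ring, "ligand_contacts_ring.tsv")
    })
    stage("stacking", {
      st <- do.call(stacking_statistics, c(list(ens), config$stacking))
      emit(st$by_residue, "stacking_by_residue.tsv")
      emit(st$by_ring, "stacking_by_ring.tsv")
      if (nrow(st$samples)) {
        sfes <- fes2d(st$samples$distance, st$samples$angle,
                      weights = st$samples$weight,
                      xbreaks = seq(0.3, 2.0, by = 0.025),
                      ybreaks = seq(0, 90, by = 3),
                      temperature_K = config$temperature_K)
        emit(tidy(sfes), "stacking_fes.tsv")
      }
    })
    stage("ring_torsions", {
      lig_rings <- names(ring_groups(ens$topology,
                                     chain = ligand_chains(ens$topology)))
      prs <- utils::combn(lig_rings, 2)
      tabs <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
        dplyr::mutate(ring_pair_torsion_pdf(ens, prs[1, j], prs[2, j]),
                      pair = paste(prs[1, j], prs[2, j], sep = "-"))
      })
      emit(tabs, "ring_torsion_pdf.tsv")
    })
    stage("cation_pi", {
      emit(cation_pi_pdf(ens), "cation_pi_pdf.tsv")
    })
  } else {
    note(sys_name, ": ligand-dependent stages skipped (no ligand declared)")
  }

  stage("convergence", {
    emit(split_half_convergence(ens, c("rg", "hbonds", "sheet_content")),
         "convergence.tsv")
  })

  stage("ccs", {
    members <- cl$clusters[[1]]$members
    subset <- members[seq_len(min(config$ccs_frames, length(members)))]
    cb <- ccs_batch(ens, subset = subset,
                    n_orientations = config$ccs_n_orientations,
                    n_points = config$ccs_n_points, seed = config$seed,
                    selection = select_atoms(ens$topology, heavy = TRUE))
    emit(cb$frames, "ccs_cluster1_frames.tsv")
    emit(cb$summary, "ccs_cluster1_summary.tsv")
    note(sys_name, sprintf(": CCS cluster-1 mean %.0f A^2", cb$summary$mean))
  })

  out
}

#' Difference tables between two completed runs
#'
#' Compares the outputs of two [run_full_analysis()] system directories
#' (e.g. without vs with ligand): per-class secondary-structure deltas,
#' contact-map difference matrices, and strand-length distribution
#' deltas, computed as `with - without`. Both runs must share the residue
#' layout and binning; mismatched dimensions are an error.
#'
#' @param run_without,run_with Paths to the two system output directories.
#' @param out_dir Optional directory for the difference tables.
#' @return List with `ss_delta`, `contact_delta` (named list of
#'   matrices), `strand_length_delta`.
#' @export
compare_conditions <- function(run_without, run_with, out_dir = NULL) {
  rd <- function(dir, name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing table ", name, " in ", dir)
    utils::read.delim(p, check.names = FALSE)
  }
  ss0 <- rd(run_without, "ss_summary.tsv")
  ss1 <- rd(run_with, "ss_summary.tsv")
  if (!identical(ss0$class, ss1$class)) stop("mismatched class sets")
  ss_delta <- tibble::tibble(class = ss0$class,
                             delta = ss1$probability - ss0$probability)

  contact_delta <- list()
  for (nm in c("contacts_inter_mcmc.tsv", "contacts_intra_mcmc.tsv",
               "contacts_inter_scsc.tsv", "contacts_intra_scsc.tsv")) {
    a <- rd(run_without, nm); b <- rd(run_with, nm)
    if (!identical(dim(a), dim(b)) || !identical(names(a), names(b))) {
      stop("mismatched contact-map layout in ", nm)
    }
    d <- as.matrix(b[, -1]) - as.matrix(a[, -1])
    rownames(d) <- a$resid
    contact_delta[[sub(".tsv$", "", nm)]] <- d
  }

  f0 <- rd(run_without, "fes_rg_hbonds.tsv")
  f1 <- rd(run_with, "fes_rg_hbonds.tsv")
  if (!isTRUE(all.equal(sort(unique(f0$x)), sort(unique(f1$x)))) ||
      !isTRUE(all.equal(sort(unique(f0$y)), sort(unique(f1$y))))) {
    stop("mismatched free-energy-surface binning between runs")
  }

  sl0 <- rd(run_without, "strand_length.tsv")
  sl1 <- rd(run_with, "strand_length.tsv")
  sl <- dplyr::full_join(
    tibble::as_tibble(sl0), tibble::as_tibble(sl1),
    by = "length", suffix = c("_without", "_with")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("probability"),
                                \(v) tidyr::replace_na(v, 0))) |>
    dplyr::mutate(delta = .data$probability_with - .data$probability_without) |>
    dplyr::arrange(.data$length)

  res <- list(ss_delta = ss_delta, contact_delta = contact_delta,
              strand_length_delta = sl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(ss_delta, file.path(out_dir, "ss_delta.tsv"))
    .write_tsv(sl, file.path(out_dir, "strand_length_delta.tsv"))
    for (nm in names(contact_delta)) {
      .write_tsv(as.data.frame(contact_delta[[nm]]),
                 file.path(out_dir, paste0(nm, "_delta.tsv")))
    }
  }
  res
}
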