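# End-to-end demo pipeline: generates the synthetic world, runs every
# analysis stage, and writes deterministic tabular outputs plus a run
# manifest. Re-running with the same config reproduces every output
# byte for byte.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# small stable polynomial hash of a string (manifest fingerprint only)
.fnv1a <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full demo pipeline on synthetic data
#'
#' Builds the synthetic protomer and filament, runs global and local ANM
#' with mode classification, ensemble RMSD comparison with region
#' detection, diffusion-tensor estimation and model-free fitting,
#' chemical-shift-perturbation scoring, and the two-state HDX comparison.
#' All numeric outputs are written as tab-separated text under
#' `out_dir`, together with a JSON manifest recording the configuration,
#' seed and a config fingerprint.
#'
#' @param config list from [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; the manifest lists every artifact.
#' @export
run_demo <- function(config = synthetic_config(), out_dir = tempfile("filadyn_demo_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  artifacts <- character(0)
  add <- function(x) artifacts <<- c(artifacts, basename(x))

  # --- structures -------------------------------------------------------
  prot <- .stage("protomer", make_protomer(config$protomer_length, seed))
  params <- helical_params(config$rise, config$twist)
  fil <- .stage("filament", build_filament(prot, params, config$n_subunits))
  add(write_structure(fil, file.path(out_dir, "pilus.pdb")))

  # --- global NMA -------------------------------------------------------
  glob <- .stage("global NMA", {
    H <- build_hessian(fil, elastic_network_params())
    modes <- compute_modes(H, n_modes = 3L)
    prof <- mode_msf(modes, 1:3)
    labels <- lapply(1:3, function(k) classify_mode(modes, fil, k))
    per_mode_sub <- lapply(1:3, function(k)
      subunit_average_msf(fil, mode_msf(modes, k)))
    list(modes = modes, prof = prof, labels = labels,
         per_mode_sub = per_mode_sub)
  })
  add(.write_tsv(data.frame(
    subunit = seq_len(config$n_subunits),
    msf_mode1 = glob$per_mode_sub[[1L]],
    msf_mode2 = glob$per_mode_sub[[2L]],
    msf_mode3 = glob$per_mode_sub[[3L]]),
    file.path(out_dir, "global_msf.tsv")))
  add(.write_tsv(data.frame(
    mode = 1:3,
    eigenvalue = glob$modes$eigenvalues[glob$modes$n_trivial + 1:3],
    label = vapply(glob$labels, `[[`, "", "label"),
    overlap_bend = vapply(glob$labels, function(l) l$overlaps[["bend"]], 0),
    overlap_twist = vapply(glob$labels, function(l) l$overlaps[["twist"]], 0),
    overlap_stretch = vapply(glob$labels, function(l) l$overlaps[["stretch"]], 0)),
    file.path(out_dir, "mode_labels.tsv")))

  # --- local NMA on an axial slice -------------------------------------
  loc <- .stage("local NMA", {
    ln <- local_nma(fil)
    ok <- !is.na(ln$central_atom_idx)
    list(res = fil$protomer$residue_ids[ok],
         msf = ln$profile$per_atom_msf[ln$central_atom_idx[ok]],
         lowest_label = ln$labels[[1L]]$label)
  })
  add(.write_tsv(data.frame(residue = loc$res, msf = loc$msf),
                 file.path(out_dir, "local_msf.tsv")))

  # --- ensemble RMSD comparison ----------------------------------------
  cmp <- .stage("ensemble comparison", {
    ensA <- make_ensemble(prot, config$ensemble_size,
                          config$coordinate_noise_sd, seed + 10L)
    protB <- prot
    shift_res <- intersect(100:110, prot$residue_ids)
    protB$ca_coords[shift_res, 1L] <- protB$ca_coords[shift_res, 1L] + 1.0
    ensB <- make_ensemble(protB, config$ensemble_size,
                          config$coordinate_noise_sd, seed + 11L)
    pa <- ensemble_rmsd_profile(ensA, reference = prot)
    pb <- ensemble_rmsd_profile(ensB, reference = prot)
    regs <- delta_rmsd_regions(pa, pb)
    list(pa = pa, pb = pb, regs = regs)
  })
  add(.write_tsv(data.frame(residue = cmp$pa$residue_ids,
                            rmsd_mean_A = cmp$pa$mean, rmsd_sd_A = cmp$pa$sd,
                            rmsd_mean_B = cmp$pb$mean, rmsd_sd_B = cmp$pb$sd),
                 file.path(out_dir, "rmsd_profile.tsv")))
  add(.write_tsv(cmp$regs, file.path(out_dir, "delta_rmsd_regions.tsv")))

  # --- relaxation: tensor + model-free ---------------------------------
  mf <- .stage("model-free", {
    truth <- default_relaxation_truth(min(110L, config$protomer_length))
    tensor_true <- diffusion_tensor(1.95e7, 2.15e7, 2.88e7)
    nh <- prot$nh_vectors[seq_len(nrow(truth)), , drop = FALSE]
    ds <- make_relaxation_dataset(truth, tensor_true, nh,
                                  noise_frac = config$relaxation_noise,
                                  seed = seed + 20L)
    tensor_fit <- estimate_diffusion_tensor(ds)
    fits <- fit_model_free(ds, tensor_fit)
    list(ds = ds, tensor = tensor_fit, fits = fits)
  })
  add(.write_tsv(mf$fits, file.path(out_dir, "model_free.tsv")))
  add(.write_tsv(data.frame(component = c("Dx", "Dy", "Dz"),
                            value_s1 = c(mf$tensor$Dx, mf$tensor$Dy,
                                         mf$tensor$Dz)),
                 file.path(out_dir, "diffusion_tensor.tsv")))

  # --- chemical shift perturbations ------------------------------------
  cspt <- .stage("CSP", .with_seed(seed + 30L, {
    n <- config$protomer_length
    ddH <- stats::rnorm(n, 0, 0.005)
    ddN <- stats::rnorm(n, 0, 0.03)
    hot <- intersect(c(100:112, 125:134), seq_len(n))
    ddH[hot] <- ddH[hot] + 0.05
    ddN[hot] <- ddN[hot] + 0.4
    data.frame(residue = seq_len(n), ddH = ddH, ddN = ddN,
               ddavg = csp(ddH, ddN))
  }))
  add(.write_tsv(cspt, file.path(out_dir, "csp.tsv")))

  # --- HDX --------------------------------------------------------------
  hdx <- .stage("HDX", {
    cond <- labeling_conditions(time_points = config$time_points)
    rates <- default_hdx_truth(prot$sequence, seed = seed + 40L)
    pmap <- make_peptide_map(prot$sequence, seed = seed + 41L)
    tabs <- make_hdx_tables(rates, pmap, cond,
                            noise_sd = config$hdx_noise_sd,
                            n_replicates = config$hdx_replicates,
                            seed = seed + 42L)
    compare_states(tabs$A, tabs$B, cond)
  })
  add(.write_tsv(hdx$peptides, file.path(out_dir, "hdx_peptides.tsv")))
  add(.write_tsv(hdx$residues, file.path(out_dir, "hdx_residues.tsv")))

  # --- manifest ---------------------------------------------------------
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "filadyn",
                   version = as.character(utils::packageVersion("filadyn")),
                   seed = seed,
                   config = config,
                   config_hash = .fnv1a(as.character(cfg_json)),
                   artifacts = artifacts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
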