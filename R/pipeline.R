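# pipeline: orchestration of holdout -> featurize -> train -> (incremental
# rounds) -> guided sampling -> realization -> evaluation, with provenance.

#' Pipeline run configuration
#'
#' @param ensemble_spec a \code{\link{toy_ensemble_spec}} describing the data.
#' @param sivae a \code{\link{sivae_config}}.
#' @param sampler a \code{\link{sampler_config}}.
#' @param realize a \code{\link{realize_config}}.
#' @param out_dir artifact directory (\code{NULL} = no files written).
#' @param references_k number of synthetic reference distograms.
#' @param references_blur reference blur width (Angstrom).
#' @param incremental_rounds incremental-learning rounds (default 1).
#' @param exclusion_rmsd holdout exclusion radius (Angstrom, default 1).
#' @param pocket optional \code{pocket_definition} for pocket-RMSD reporting.
#' @param save_artifacts write model checkpoint, references and realized PDBs.
#' @return a \code{run_config}.
#' @export
run_config <- function(ensemble_spec = toy_ensemble_spec(),
                       sivae = sivae_config(), sampler = sampler_config(),
                       realize = realize_config(), out_dir = NULL,
                       references_k = 5, references_blur = 0.5,
                       incremental_rounds = 1, exclusion_rmsd = 1.0,
                       pocket = NULL, save_artifacts = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

config_digest <- function(cfg) {
  s <- jsonlite::toJSON(rapply(unclass(cfg), unclass, how = "replace"),
                        auto_unbox = TRUE, digits = 10, null = "null",
                        force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% 2147483647)
}

# Embedded training matrix for a holdout split, with snapshot-level hygiene:
# any individual snapshot within the exclusion radius of the target is
# dropped as well (belt-and-braces beyond the crystal-level rule).
training_matrix <- function(ens, split, target, exclusion_rmsd,
                            use_raw_angles = FALSE) {
  maps <- list(); origin <- character(0); rmsds <- numeric(0)
  for (cid in split$train_snapshots) {
    for (s in ens$snapshots[[cid]]) {
      r <- ca_rmsd(s, target)
      if (r < exclusion_rmsd) next
      maps[[length(maps) + 1L]] <- coords_to_features(s)
      origin <- c(origin, cid)
      rmsds <- c(rmsds, r)
    }
  }
  if (length(maps) == 0) stop("no training snapshots survive the holdout rule",
                              call. = FALSE)
  X <- embed_dataset(maps, use_raw_angles)
  attr(X, "origin") <- origin
  attr(X, "rmsd_to_target") <- rmsds
  X
}

#' Audit holdout hygiene
#'
#' Recomputes the CA RMSD of every training item (crystals and snapshots in
#' the manifest) to the target and counts violations of the exclusion rule.
#'
#' @param ens a \code{toy_ensemble}.
#' @param split a \code{holdout_split}.
#' @param exclusion_rmsd exclusion radius (Angstrom).
#' @return list: \code{violations} (count), \code{n_items} audited.
#' @export
audit_holdout <- function(ens, split, exclusion_rmsd = 1.0) {
  target <- ens$crystals[[split$target]]
  v <- 0L; n <- 0L
  for (cid in split$train_crystals) {
    n <- n + 1L
    if (ca_rmsd(ens$crystals[[cid]], target) < exclusion_rmsd) v <- v + 1L
  }
  list(violations = v, n_items = n)
}

#' Run the full method for one held-out target
#'
#' Executes holdout -> featurization -> VAE training -> incremental rounds ->
#' guided ensemble generation -> 3D realization -> evaluation. All stages are
#' seeded from the configs, so a rerun reproduces the report exactly.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param target_id crystal id to hold out.
#' @param ens optional pre-built \code{toy_ensemble} (else generated from
#'   \code{cfg$ensemble_spec}).
#' @return an \code{evaluation_run}: list with \code{report} (one-row
#'   data.frame), \code{curve} (closest-vs-n data.frame), \code{model},
#'   \code{generated}, \code{realized} (list of structures), \code{split},
#'   \code{references}, \code{audit}, \code{run_id}.
#' @export
run_target <- function(cfg, target_id, ens = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(ens)) ens <- make_toy_ensemble(cfg$ensemble_spec)
  target <- ens$crystals[[target_id]]
  if (is.null(target)) stop("unknown target id: ", target_id, call. = FALSE)
  split <- make_holdout(ens, target_id, cfg$exclusion_rmsd)
  X <- training_matrix(ens, split, target, cfg$exclusion_rmsd,
                       cfg$sivae$use_raw_angles)
  audit0 <- audit_holdout(ens, split, cfg$exclusion_rmsd)
  # snapshot-level audit over the actual training manifest
  audit0$snapshot_violations <-
    sum(attr(X, "rmsd_to_target") < cfg$exclusion_rmsd)
  audit0$min_train_rmsd <- min(attr(X, "rmsd_to_target"))
  audit0$n_items <- audit0$n_items + nrow(X)
  model <- sivae_train(cfg$sivae, X)
  refs <- make_reference_distograms(target, cfg$references_k,
                                    cfg$references_blur,
                                    seed = cfg$sampler$seed)
  rounds <- 0L
  while (rounds < cfg$incremental_rounds) {
    rounds <- rounds + 1L
    model <- incremental_round(cfg, model, X, refs)
  }
  gen <- generate_ensemble(model, refs, cfg$sampler)
  realizer <- realize_adapter(cfg = cfg$realize)
  realized_res <- lapply(gen$features, realizer)
  ok <- vapply(realized_res, function(r) !is.null(r$structure), logical(1))
  realized <- lapply(realized_res[ok], function(r) r$structure)
  if (length(realized) == 0) stop("no sample could be realized", call. = FALSE)
  # evaluation
  crmsd <- vapply(split$train_crystals,
                  function(id) ca_rmsd(ens$crystals[[id]], target), numeric(1))
  srmsd <- min(vapply(split$train_snapshots, function(id)
    min(vapply(ens$snapshots[[id]], ca_rmsd, numeric(1), b = target)),
    numeric(1)))
  closest_gen <- closest_in_ensemble(realized, target, "ca")
  pocket_gen <- NA_real_
  if (!is.null(cfg$pocket))
    pocket_gen <- closest_in_ensemble(realized, target, "pocket",
                                      pocket = cfg$pocket)$rmsd
  curve <- curve_closest_vs_n(realized, target)
  run_id <- paste0(target_id, "-", config_digest(cfg))
  report <- data.frame(target = target_id,
                       closest_train_crystal = min(crmsd),
                       closest_train_snapshot = srmsd,
                       closest_generated = closest_gen$rmsd,
                       closest_generated_pocket = pocket_gen,
                       ensemble_size = length(realized),
                       n_train = nrow(X),
                       seed = cfg$sampler$seed,
                       run_id = run_id)
  out <- structure(list(report = report, curve = curve, model = model,
                        generated = gen, realized = realized, split = split,
                        references = refs, audit = audit0, run_id = run_id,
                        realization = realized_res),
                   class = "evaluation_run")
  if (!is.null(cfg$out_dir)) write_run_artifacts(out, cfg)
  out
}

write_run_artifacts <- function(run, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(cfg$out_dir, run$run_id)
  utils::write.table(run$report, paste0(base, "-report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$curve, paste0(base, "-curve.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(run_id = run$run_id,
                   target = run$report$target,
                   config_digest = config_digest(cfg),
                   seeds = list(data = cfg$ensemble_spec$seed,
                                sivae = cfg$sivae$seed,
                                sampler = cfg$sampler$seed),
                   holdout = list(target = run$split$target,
                                  train_crystals = run$split$train_crystals,
                                  excluded = run$split$excluded,
                                  audit_violations = run$audit$violations),
                   ensemble_size = run$report$ensemble_size,
                   n_train = run$report$n_train)
  jsonlite::write_json(manifest, paste0(base, "-manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(cfg$save_artifacts)) {
    sivae_save(run$model, paste0(base, "-model.rds"))
    save_references(run$references, paste0(base, "-references.rds"))
    pdb_dir <- paste0(base, "-ensemble")
    dir.create(pdb_dir, showWarnings = FALSE)
    for (i in seq_along(run$realized))
      write_backbone_pdb(run$realized[[i]],
                         file.path(pdb_dir, sprintf("sample_%04d.pdb", i)))
  }
  invisible(base)
}

#' One incremental-learning round
#'
#' Generates the configured number of filtered samples with the current
#' model, appends their feature maps to the training set, and retrains a
#' fresh model from scratch on the union.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param model the trained model from the previous round.
#' @param train_X embedded training matrix of the previous round.
#' @param references reference distograms for the guidance score.
#' @return a new \code{sivae_model} trained on the augmented set.
#' @export
incremental_round <- function(cfg, model, train_X, references) {
  scfg <- cfg$sampler
  if (scfg$n_samples > 0) {
    gen <- generate_ensemble(model, references, scfg)
    if (length(gen$features) > 0) {
      Xg <- embed_dataset(gen$features, cfg$sivae$use_raw_angles)
      atts <- attributes(train_X)[c("L", "cutoff", "sequence")]
      train_X <- rbind(train_X, Xg)
      attributes(train_X)[names(atts)] <- atts
    }
  }
  sivae_train(cfg$sivae, train_X)
}

#' Closest-sample RMSD as a function of ensemble size
#'
#' Running minimum of the metric over the first n samples, in generation
#' order; non-increasing by construction.
#'
#' @param ensemble ordered nonempty list of \code{backbone_structure}s.
#' @param target a \code{backbone_structure}.
#' @param metric "ca" or "pocket".
#' @param pocket required for \code{metric = "pocket"}.
#' @return data.frame with columns \code{n} and \code{rmsd}.
#' @export
curve_closest_vs_n <- function(ensemble, target, metric = c("ca", "pocket"),
                               pocket = NULL) {
  metric <- match.arg(metric)
  if (length(ensemble) == 0) stop("empty ensemble", call. = FALSE)
  vals <- vapply(ensemble, function(s)
    if (metric == "ca") ca_rmsd(s, target) else pocket_rmsd(s, target, pocket),
    numeric(1))
  data.frame(n = seq_along(vals), rmsd = cummin(vals))
}

#' 2D PCA projection of the latent space
#'
#' Encodes every structure set to posterior means, fits principal components
#' on the first (training) set and projects all sets onto PC1/PC2.
#'
#' @param model a trained \code{sivae_model}.
#' @param sets named list; each element a list of \code{template_features}
#'   or an embedded matrix. The first set defines the principal axes.
#' @param plot draw a base-graphics scatter (convenience side effect).
#' @return data.frame with columns \code{set}, \code{PC1}, \code{PC2}.
#' @export
latent_pca_projection <- function(model, sets, plot = FALSE) {
  stopifnot(is.list(sets), length(sets) >= 1)
  mus <- lapply(sets, function(s) sivae_encode(model, s)$mu)
  if (nrow(mus[[1]]) < 3) stop("need at least 3 training points for PCA",
                               call. = FALSE)
  pc <- stats::prcomp(mus[[1]], center = TRUE, scale. = FALSE)
  proj <- lapply(seq_along(mus), function(k) {
    p <- stats::predict(pc, mus[[k]])[, 1:2, drop = FALSE]
    data.frame(set = names(sets)[k] %||% as.character(k),
               PC1 = p[, 1], PC2 = p[, 2])
  })
  out <- do.call(rbind, proj)
  rownames(out) <- NULL
  if (plot) {
    cols <- seq_along(sets)
    graphics::plot(out$PC1, out$PC2,
                   col = cols[match(out$set, unique(out$set))],
                   pch = 16, xlab = "PC1", ylab = "PC2",
                   main = "Latent space PCA")
    graphics::legend("topright", legend = unique(out$set),
                     col = cols, pch = 16, bty = "n")
  }
  out
}

#' Canonical hinge-helix benchmark configuration
#'
#' The evaluation conditions used throughout the package's own validation:
#' a 48-residue hinge helix with 6 crystal conformations at hinge angles
#' evenly spaced on [-30, 30] degrees (adjacent CA RMSD just above the
#' 1 Angstrom holdout rule), 30 snapshots per crystal in 5
#' pseudo-trajectories at 0.3 Angstrom scale; a 16-dimensional-latent SI-VAE
#' trained for 22 epochs; 500 guided samples per target, each optimized for
#' up to 35 iterations within the d_max = 10 trust region. Interior crystals
#' (2-5) serve as held-out targets. Problem sizes are chosen so a full
#' 4-target evaluation runs in minutes on one CPU; see the methods vignette.
#'
#' @param seed integer master seed; data, training and sampling seeds are
#'   derived from it.
#' @param n_samples guided samples per target (default 500).
#' @return a \code{\link{run_config}}.
#' @export
toy_benchmark_config <- function(seed = 1, n_samples = 500) {
  seed <- as.integer(seed) %% 100000L
  run_config(
    ensemble_spec = toy_ensemble_spec(n_residues = 48, n_crystals = 6,
                                      hinge_angles = seq(-30, 30,
                                                         length.out = 6),
                                      snapshots_per_crystal = 30,
                                      seed = seed + 10L),
    sivae = sivae_config(latent_dim = 16, block_features = 64,
                         n_resnet_blocks = 3, batch_size = 64, epochs = 22,
                         lr = 2e-3, seed = seed + 20L),
    sampler = sampler_config(n_samples = n_samples, max_iters = 35,
                             patience = 8, lr = 0.3, seed = seed + 30L,
                             chunk_size = 250, diversity_tau = 0.1),
    realize = realize_config(refine_iters = 60),
    incremental_rounds = 0)
}
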