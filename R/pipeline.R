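#' Pipeline run configuration
#'
#' @param contigs Path to the assembly FASTA.
#' @param depth_paths Character vector of per-sample depth inputs (BED or
#'   BAM), one per sample.
#' @param scg Path to the single-copy marker hit TSV (`NULL` for
#'   unconstrained clustering and degenerate selection).
#' @param outdir Output directory.
#' @param mode Binning mode: `"co-assembly"` (pooled assembly, >= 1 depth
#'   input), `"single-sample"` (exactly 1) or `"multi-sample"`
#'   (sample-specific contigs with >= 2 cross-sample depth inputs,
#'   aggregated coverage). The coverage machinery is identical in all
#'   modes; the mode gates input arity.
#' @param min_contig_len Minimum contig length (default 1000 bp).
#' @param n_aug Augmented views per contig (default 5).
#' @param encoder_cfg An [encoder_config()].
#' @param train_cfg A [train_config()].
#' @param grid A [sweep_grid()].
#' @param knn_k Neighbours for the clustering graph (`NULL` = default).
#' @param min_bin_bp Final bin-size filter (default 200000).
#' @param seed Global seed; stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(contigs, depth_paths, scg = NULL, outdir,
                       mode = c("co-assembly", "single-sample", "multi-sample"),
                       min_contig_len = 1000L, n_aug = 5L,
                       encoder_cfg = encoder_config(),
                       train_cfg = train_config(), grid = sweep_grid(),
                       knn_k = NULL, min_bin_bp = 200000, seed = 1L) {
  mode <- match.arg(mode)
  M <- length(depth_paths)
  if (mode == "single-sample" && M != 1) {
    stop("single-sample mode requires exactly one depth input, got ", M)
  }
  if (mode == "multi-sample" && M < 2) {
    stop("multi-sample mode requires >= 2 depth inputs (cross-sample coverage), got ", M)
  }
  if (M < 1) stop("at least one depth input is required")
  structure(list(contigs = contigs, depth_paths = depth_paths, scg = scg,
                 outdir = outdir, mode = mode,
                 min_contig_len = as.integer(min_contig_len),
                 n_aug = as.integer(n_aug), encoder_cfg = encoder_cfg,
                 train_cfg = train_cfg, grid = grid, knn_k = knn_k,
                 min_bin_bp = min_bin_bp, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full binning pipeline
#'
#' Executes augment -> features -> train -> embed -> cluster sweep ->
#' selection -> bin-size filter -> write, and writes a `manifest.json`
#' recording the configuration, seed, assembly N50, chosen temperature,
#' selected sweep parameters, stage counts and timings — enough to
#' reproduce the run from the raw inputs.
#'
#' @param cfg A [run_config()].
#' @param verbose Log stage progress.
#' @return List with `assignment` (final bins after the size filter),
#'   `sweep` (diagnostics), `model`, `embeddings` and `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  t_all <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  contigs <- tick("read", read_fasta(cfg$contigs, cfg$min_contig_len))
  if (verbose) cb_log("read", "%d contigs, N50 %d", length(contigs), contigs$n50)
  tracks <- tick("depth", lapply(cfg$depth_paths, read_depth, contigs = contigs))
  scg <- tick("scg", if (is.null(cfg$scg)) {
    scg_table(data.frame(contig_id = character(0), marker_id = character(0)),
              marker_universe = character(0))
  } else read_scg_table(cfg$scg, contigs))

  views <- tick("augment", augment_contigs(contigs, n_aug = cfg$n_aug,
                                           min_frag_len = cfg$min_contig_len,
                                           seed = derive_seed(cfg$seed, "augment")))
  feats <- tick("features", build_features(views, tracks))
  tcfg <- cfg$train_cfg
  tcfg$seed <- derive_seed(cfg$seed, "train")
  model <- tick("train", train_encoder(feats, cfg$encoder_cfg, tcfg,
                                       assembly_n50 = contigs$n50,
                                       verbose = verbose))
  Z <- tick("embed", embed_contigs(model, feats))
  sweep <- tick("cluster", run_sweep_and_select(
    Z, scg, contigs$lengths, grid = cfg$grid, knn_k = cfg$knn_k,
    seed = derive_seed(cfg$seed, "leiden")))
  final <- tick("filter", filter_small_bins(sweep$assignment, contigs$lengths,
                                            cfg$min_bin_bp))
  if (verbose) {
    cb_log("filter", "%d bins (>= %g bp) from %d pre-filter",
           length(final$bin_sizes), cfg$min_bin_bp,
           length(sweep$assignment$bin_sizes))
  }
  final <- tick("write", write_bins(final, contigs, cfg$outdir))

  manifest <- list(
    package_version = as.character(utils::packageVersion("contrabin")),
    mode = cfg$mode, seed = cfg$seed,
    inputs = list(contigs = cfg$contigs, depth = cfg$depth_paths,
                  scg = cfg$scg),
    n_contigs = length(contigs), n50 = contigs$n50, n_samples = length(tracks),
    tau = model$tau, epochs_run = length(model$loss_history),
    final_loss = unname(utils::tail(model$loss_history, 1)),
    seed_marker = sweep$seed_marker,
    n_fixed_contigs = length(sweep$fixed_contigs),
    selected = sweep$assignment$params,
    n_bins_prefilter = length(sweep$assignment$bin_sizes),
    n_bins_final = length(final$bin_sizes),
    min_bin_bp = cfg$min_bin_bp,
    config = list(min_contig_len = cfg$min_contig_len, n_aug = cfg$n_aug,
                  encoder = unclass(cfg$encoder_cfg),
                  train = unclass(cfg$train_cfg), grid = unclass(cfg$grid),
                  knn_k = cfg$knn_k),
    timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t_all, 2))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  utils::write.table(sweep$diagnostics,
                     file.path(cfg$outdir, "sweep_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(assignment = final, sweep = sweep, model = model, embeddings = Z,
       manifest = manifest)
}
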