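# Configuration handling and the end-to-end pipeline driver shared by the
# command-line interface and scripted use.

#' Derive a deterministic per-stage seed from a run seed
#'
#' All pipeline randomness flows from one top-level seed; each stage gets its
#' own stream via a small string hash, so stages can be re-run independently
#' without coupling their draws. The result stays below 2^31.
#'
#' @param seed Integer run seed.
#' @param stage Stage name (e.g. `"simulate"`, `"train_gene"`).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Load a run configuration
#'
#' Reads a YAML key-value file and overlays named overrides (command-line
#' flags win over file values). The effective configuration can be frozen
#' next to every output for provenance.
#'
#' @param path Optional YAML file.
#' @param overrides Named list of overriding values.
#' @return Named list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg
}

#' @rdname load_run_config
#' @param cfg Effective configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full two-stage pipeline on a simulated genome
#'
#' Simulates a genome and a labeled peptide set, trains both classifiers,
#' predicts and greedily resolves gene calls, translates them, classifies
#' the resulting peptides and profiles their physicochemical properties —
#' the complete workflow at a chosen scale, fully determined by `seed`.
#'
#' @param seed Run seed; every stage derives its own stream from it.
#' @param genome_len,n_genes,codon_bias_strength,gc_background Genome
#'   simulation scale.
#' @param n_pep Peptide-set size per class.
#' @param gene_config A [gene_model_config()].
#' @param pep_config A [peptide_model_config()].
#' @param pep_lr Learning rate used for the from-scratch peptide run.
#' @param task Peptide task label.
#' @return List with the simulation, trained models, calls, peptide scores,
#'   property profile and held-out evaluation tibbles.
#' @export
run_pipeline <- function(seed = 1L, genome_len = 20000L, n_genes = 20L,
                         codon_bias_strength = 50, gc_background = 0.5,
                         n_pep = 150L,
                         gene_config = gene_model_config(
                           max_epochs = 10L, seed = derive_seed(seed, "gene")),
                         pep_config = peptide_model_config(
                           cnn_filters = c(64L, 32L, 16L), lstm_hidden = 16L,
                           mlp_widths = c(32L, 16L), batch_size = 16L,
                           max_epochs = 6L, max_len = 42L, lr = 1e-3,
                           seed = derive_seed(seed, "pep")),
                         pep_lr = NULL, task = "ACP") {
  sim <- simulate_genome(length = genome_len, n_genes = n_genes,
                         gc_background = gc_background,
                         codon_bias_strength = codon_bias_strength,
                         seed = derive_seed(seed, "simulate"))
  cands <- scan_orfs(sim$genome)
  dataset <- make_orf_dataset(cands, sim$truth,
                              seed = derive_seed(seed, "dataset"))
  split <- stratified_split(dataset, ratio = 0.7,
                            seed = derive_seed(seed, "split"))
  x_tr <- featurize_orfs(split$train)
  x_te <- featurize_orfs(split$test)
  gene_model <- train_gene_model(x_tr, split$train$label, gene_config,
                                 validation = list(x = x_te,
                                                   y = split$test$label))
  x_all <- featurize_orfs(cands)
  scored <- dplyr::bind_cols(cands,
                             probability = predict_orfs(gene_model,
                                                        x_all)$probability)
  calls <- greedy_resolve(scored)
  gene_eval <- evaluate_calls(calls, sim$truth, n_candidates = nrow(cands))
  peptides <- simulate_peptides(n_pos = n_pep, n_neg = n_pep,
                                seed = derive_seed(seed, "peptides"))
  pep_split <- stratified_split(peptides, ratio = 0.8,
                                seed = derive_seed(seed, "pep_split"))
  if (!is.null(pep_lr)) pep_config$lr <- pep_lr
  pep_model <- train_peptide_model(pep_split$train, task = task,
                                   config = pep_config,
                                   provider = embedding_provider(dim = 32L))
  pep_scores <- predict_peptides(pep_model, pep_split$test)
  called_peps <- translate_calls(calls)
  called_scores <- predict_peptides(pep_model, called_peps)
  profile <- profile_peptides(called_peps)
  list(simulation = sim, candidates = cands, gene_model = gene_model,
       calls = calls, gene_eval = gene_eval, pep_model = pep_model,
       pep_holdout = pep_scores, pep_holdout_truth = pep_split$test,
       called_peptides = called_peps, called_scores = called_scores,
       profile = profile)
}
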