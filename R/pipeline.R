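#' @include synthetic-data.R
NULL

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#' Values are resolved in order: package defaults, then a JSON config
#' `file`, then named arguments in `...` (mirroring command-line flag
#' overrides).
#'
#' @param ... named overrides of individual fields (see Details).
#' @param file optional path to a JSON object with the same field names.
#' @details Fields: `threshold` (Jaccard sparsification, 0), `p`, `q`
#'   (signed-walk biases, 1), `alpha`, `beta` (unsigned-walk biases, 1),
#'   `walksPerNode` (10), `walkLength` (80), `dim` (32), `window` (5),
#'   `epochs` (5), `negative` (5), `lr` (0.025), `folds` (5), `lambda`
#'   (1), `topK` (1, 3, 5), `unsignedOnly` (FALSE), `seed` (1).
#' @return Validated list of class `RunConfig`.
#' @export
runConfig <- function(..., file = NULL) {
  cfg <- list(threshold = 0, p = 1, q = 1, alpha = 1, beta = 1,
              walksPerNode = 10L, walkLength = 80L, dim = 32L,
              window = 5L, epochs = 5L, negative = 5L, lr = 0.025,
              folds = 5L, lambda = 1, topK = c(1L, 3L, 5L),
              unsignedOnly = FALSE, seed = 1L)
  if (!is.null(file)) {
    over <- jsonlite::read_json(file, simplifyVector = TRUE)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  stopifnot(cfg$threshold >= 0, cfg$threshold < 1, cfg$folds >= 2,
            cfg$lambda > 0, all(cfg$topK >= 1))
  ## walkParams() validates the walk block
  walkParams(cfg$p, cfg$q, cfg$alpha, cfg$beta, cfg$walksPerNode,
             cfg$walkLength)
  structure(cfg, class = "RunConfig")
}

.cfgWalkParams <- function(cfg)
  walkParams(cfg$p, cfg$q, cfg$alpha, cfg$beta, cfg$walksPerNode,
             cfg$walkLength)

.log <- function(outDir, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(outDir))
    cat(msg, "\n", file = file.path(outDir, "run.log"), append = TRUE)
  invisible(NULL)
}

#' Build and serialize the four drug subnetworks
#'
#' Reads the bundle tables from `inputDir`, builds the three Jaccard
#' subnetworks and the signed subnetwork, and writes them as edge-list
#' TSVs under `outDir` (`network_<name>.tsv`).
#'
#' @param inputDir directory holding the four input tables (see
#'   [readBundle()]).
#' @param outDir output directory, created if missing.
#' @param config a [runConfig()] list.
#' @return The assembled [DrugHIN-class], invisibly.
#' @export
pipelineBuildNetwork <- function(inputDir, outDir, config = runConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  b <- readBundle(inputDir)
  hin <- assembleHIN(
    buildUnsignedSubnetwork(b$chemical, config$threshold),
    buildUnsignedSubnetwork(b$labels, config$threshold),
    buildUnsignedSubnetwork(b$target, config$threshold),
    buildSignedSubnetwork(b$assoc))
  for (nm in .hinNames)
    writeEdgeList(subnetwork(hin, nm),
                  file.path(outDir, paste0("network_", nm, ".tsv")))
  .log(outDir, "build-network: %d drugs; edges %s", length(drugIds(hin)),
       paste(vapply(.hinNames,
                    function(nm) nrow(subnetwork(hin, nm)@edges),
                    integer(1)), collapse = "/"))
  invisible(hin)
}

#' Sample the walk corpus from serialized subnetworks
#'
#' Reads the edge lists written by [pipelineBuildNetwork()] from `outDir`,
#' samples the pooled corpus and writes it to `corpus.txt`.
#'
#' @inheritParams pipelineBuildNetwork
#' @param outDir directory holding the `network_*.tsv` stage outputs.
#' @return The [WalkCorpus-class], invisibly.
#' @export
pipelineWalk <- function(outDir, config = runConfig()) {
  nets <- lapply(.hinNames, function(nm)
    readEdgeList(file.path(outDir, paste0("network_", nm, ".tsv"))))
  names(nets) <- .hinNames
  hin <- assembleHIN(nets$chemical, nets$side_effect, nets$target,
                     nets$signed_target)
  corpus <- buildCorpus(hin, .cfgWalkParams(config), seed = config$seed,
                        unsignedOnly = isTRUE(config$unsignedOnly))
  writeCorpus(corpus, file.path(outDir, "corpus.txt"))
  .log(outDir, "walk: %d walks, %d tokens%s", length(walks(corpus)),
       sum(lengths(walks(corpus))),
       if (isTRUE(config$unsignedOnly)) " (unsigned-only)" else "")
  invisible(corpus)
}

#' Train and serialize embeddings from the corpus stage output
#'
#' @inheritParams pipelineWalk
#' @return The [EmbeddingSet-class], invisibly.
#' @export
pipelineEmbed <- function(outDir, config = runConfig()) {
  corpus <- readCorpus(file.path(outDir, "corpus.txt"))
  emb <- trainSkipgram(corpus, dim = config$dim, window = config$window,
                       epochs = config$epochs, negative = config$negative,
                       lr = config$lr, seed = config$seed)
  writeEmbeddings(emb, file.path(outDir, "embeddings.txt"))
  .log(outDir, "embed: %d drugs, d = %d, final loss %.4f",
       nrow(embeddingMatrix(emb)), embeddingDim(emb),
       emb@meta$finalLoss)
  invisible(emb)
}

#' Cross-validated evaluation stage
#'
#' Runs the drug-wise cross-validation of [crossValidate()] on the bundle
#' in `inputDir` and writes `scores.tsv` (the score table) and
#' `metrics.json` (merged AUROC, per-side-effect AUROCs, Top-K hit
#' counts) under `outDir`.
#'
#' @inheritParams pipelineBuildNetwork
#' @return The metrics list, invisibly.
#' @export
pipelineEvaluate <- function(inputDir, outDir, config = runConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  b <- readBundle(inputDir)
  tab <- crossValidate(b$chemical, b$target, b$assoc, b$labels,
                       nFolds = config$folds,
                       params = .cfgWalkParams(config),
                       dim = config$dim, window = config$window,
                       epochs = config$epochs, negative = config$negative,
                       lr = config$lr, lambda = config$lambda,
                       threshold = config$threshold, seed = config$seed,
                       unsignedOnly = isTRUE(config$unsignedOnly))
  writeScoreTable(tab, file.path(outDir, "scores.tsv"))
  rep <- metricsReport(tab, topK = config$topK)
  jsonlite::write_json(
    list(mergedAuroc = rep$mergedAuroc,
         topK = as.list(rep$topK),
         perSideEffect = rep$perSideEffect,
         config = unclass(config)),
    file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  .log(outDir, "evaluate: merged AUROC %.4f; top-K hits %s",
       rep$mergedAuroc, paste(rep$topK, collapse = "/"))
  invisible(rep)
}

#' Run the full pipeline end to end
#'
#' Chains [pipelineBuildNetwork()], [pipelineWalk()], [pipelineEmbed()]
#' (full-data artifacts for inspection) and [pipelineEvaluate()] (the
#' cross-validated metrics).  Each stage writes its outputs under
#' `outDir`, so any stage can be re-run from the serialized artifacts.
#'
#' @inheritParams pipelineBuildNetwork
#' @return The metrics list from the evaluation stage, invisibly.
#' @export
runPipeline <- function(inputDir, outDir, config = runConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .log(outDir, "run-all: rwshin %s, seed %d, unsignedOnly=%s",
       as.character(utils::packageVersion("rwshin")), config$seed,
       isTRUE(config$unsignedOnly))
  pipelineBuildNetwork(inputDir, outDir, config)
  pipelineWalk(outDir, config)
  pipelineEmbed(outDir, config)
  invisible(pipelineEvaluate(inputDir, outDir, config))
}
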