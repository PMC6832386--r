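#' @include prediction.R
NULL

#' Specification of a synthetic drug-information bundle
#'
#' Describes a world in which drugs fall into groups that share a block of
#' targets and a block of fingerprint bits, and in which side-effects
#' depend on the SIGN of the action mode, not merely on which targets are
#' hit: within each group a `signFlipFraction` subset acts with opposite
#' (inhibitory, -1) modes on the group's targets, and side-effect blocks
#' are assigned per (group, sign) class.  Unsigned target profiles are
#' therefore identical within a group while true labels differ by sign --
#' the situation where mode-of-action information is decisive.
#'
#' @param nDrugs,nTargets,nSideEffects,nGroups positive counts (defaults
#'   120, 60, 40, 6).
#' @param signFlipFraction fraction of each group acting with opposite
#'   modes on the group targets, in \[0, 1\] (default 0.5).
#' @param labelNoise probability of flipping each side-effect label, in
#'   \[0, 1) (default 0.05).
#' @param fingerprintBits number of chemical fingerprint bits (default
#'   200).
#' @param bitCorruption probability of flipping each fingerprint bit, in
#'   \[0, 1) (default 0.1).
#' @param seed integer seed making the bundle fully reproducible.
#' @return Validated list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nDrugs = 120, nTargets = 60, nSideEffects = 40,
                          nGroups = 6, signFlipFraction = 0.5,
                          labelNoise = 0.05, fingerprintBits = 200,
                          bitCorruption = 0.1, seed = 1L) {
  stopifnot(nDrugs >= 1, nTargets >= 1, nSideEffects >= 1, nGroups >= 1,
            nGroups <= nDrugs, nGroups <= nTargets,
            signFlipFraction >= 0, signFlipFraction <= 1,
            labelNoise >= 0, labelNoise < 1,
            fingerprintBits >= nGroups,
            bitCorruption >= 0, bitCorruption < 1)
  structure(list(nDrugs = as.integer(nDrugs),
                 nTargets = as.integer(nTargets),
                 nSideEffects = as.integer(nSideEffects),
                 nGroups = as.integer(nGroups),
                 signFlipFraction = signFlipFraction,
                 labelNoise = labelNoise,
                 fingerprintBits = as.integer(fingerprintBits),
                 bitCorruption = bitCorruption,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a complete synthetic input bundle
#'
#' See [syntheticSpec()] for the generative model.  Per-term side-effect
#' base rates are drawn from a long-tailed distribution, so a few terms
#' are common across classes and most are rare, imitating the skewed
#' marginals of real pharmacovigilance data.
#'
#' @param spec a [syntheticSpec()] object.
#' @return List of class `SyntheticBundle` with components `chemical`,
#'   `target` (unsigned binary [BinaryProfileSet-class] objects), `labels`
#'   (side-effect [BinaryProfileSet-class]), `modeRecords` (long-format
#'   data.frame feeding [buildSignedAssociationMatrix()]), `assoc` (the
#'   planted [SignedAssociationMatrix-class]), and the planted truth
#'   `group`, `actionSign` and `classId` per drug.
#' @examples
#' b <- generateBundle(syntheticSpec(nDrugs = 24, nGroups = 3, seed = 7))
#' table(b$group, b$actionSign)
#' @export
generateBundle <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    drugs <- sprintf("D%03d", seq_len(spec$nDrugs))
    targets <- sprintf("T%03d", seq_len(spec$nTargets))
    terms <- sprintf("SE%03d", seq_len(spec$nSideEffects))
    bits <- sprintf("fp%03d", seq_len(spec$fingerprintBits))

    group <- sort(rep(seq_len(spec$nGroups),
                      length.out = spec$nDrugs))
    tgtBlock <- sort(rep(seq_len(spec$nGroups),
                         length.out = spec$nTargets))
    bitBlock <- sort(rep(seq_len(spec$nGroups),
                         length.out = spec$fingerprintBits))

    ## sign assignment: a signFlipFraction subset of each group acts with
    ## -1 instead of +1 on the group's targets
    actionSign <- rep(1L, spec$nDrugs)
    for (g in seq_len(spec$nGroups)) {
      members <- which(group == g)
      nFlip <- round(spec$signFlipFraction * length(members))
      if (nFlip > 0)
        actionSign[sample(members, nFlip)] <- -1L
    }

    A <- matrix(0L, spec$nDrugs, spec$nTargets,
                dimnames = list(drugs, targets))
    for (i in seq_len(spec$nDrugs))
      A[i, tgtBlock == group[i]] <- actionSign[i]

    ## chemical fingerprints: group bit block, then symmetric corruption
    FP <- matrix(0L, spec$nDrugs, spec$fingerprintBits,
                 dimnames = list(drugs, bits))
    for (i in seq_len(spec$nDrugs))
      FP[i, bitBlock == group[i]] <- 1L
    if (spec$bitCorruption > 0) {
      flip <- matrix(runif(length(FP)) < spec$bitCorruption,
                     nrow(FP), ncol(FP))
      FP <- (FP + flip) %% 2L
      storage.mode(FP) <- "integer"
      dimnames(FP) <- list(drugs, bits)
    }

    ## side-effect ownership per (group, sign) class; long-tailed base
    ## rates: most terms belong to few classes, a handful are near-universal
    classId <- (group - 1L) * 2L + (actionSign < 0) + 1L
    nClasses <- 2L * spec$nGroups
    base <- runif(spec$nSideEffects)^3
    owns <- matrix(runif(nClasses * spec$nSideEffects) <
                     rep(base, each = nClasses),
                   nClasses, spec$nSideEffects)
    primary <- rep(seq_len(nClasses), length.out = spec$nSideEffects)
    owns[cbind(primary, seq_len(spec$nSideEffects))] <- TRUE

    Y <- matrix(0L, spec$nDrugs, spec$nSideEffects,
                dimnames = list(drugs, terms))
    for (i in seq_len(spec$nDrugs))
      Y[i, ] <- as.integer(owns[classId[i], ])
    if (spec$labelNoise > 0) {
      flip <- matrix(runif(length(Y)) < spec$labelNoise, nrow(Y), ncol(Y))
      Y <- (Y + flip) %% 2L
      storage.mode(Y) <- "integer"
      dimnames(Y) <- list(drugs, terms)
    }

    assoc <- SignedAssociationMatrix(A)
    structure(list(chemical = BinaryProfileSet(FP, "chemical"),
                   target = BinaryProfileSet(
                     matrix(as.integer(A != 0L), nrow(A), ncol(A),
                            dimnames = dimnames(A)), "target"),
                   labels = BinaryProfileSet(Y, "side_effect"),
                   modeRecords = assocToModeRecords(assoc),
                   assoc = assoc,
                   group = stats::setNames(group, drugs),
                   actionSign = stats::setNames(actionSign, drugs),
                   classId = stats::setNames(classId, drugs),
                   spec = spec),
              class = "SyntheticBundle")
  })
}

#' Write a synthetic bundle to disk in the package's TSV formats
#'
#' Writes `chemical.tsv`, `target.tsv`, `side_effects.tsv` (binary profile
#' tables readable by [readBinaryProfile()]), `mode_records.tsv`
#' (readable by [readModeRecords()]) and a `manifest.json` recording the
#' generating spec and seed.
#'
#' @param bundle a `SyntheticBundle` from [generateBundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBinaryProfile(bundle$chemical, file.path(dir, "chemical.tsv"))
  writeBinaryProfile(bundle$target, file.path(dir, "target.tsv"))
  writeBinaryProfile(bundle$labels, file.path(dir, "side_effects.tsv"))
  writeModeRecords(bundle$modeRecords, file.path(dir, "mode_records.tsv"))
  jsonlite::write_json(unclass(bundle$spec),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read the four input tables of a bundle directory
#'
#' @param dir directory written by [writeBundle()] (or hand-prepared with
#'   the same file names).
#' @return List with `chemical`, `target`, `labels`
#'   ([BinaryProfileSet-class]) and `assoc`
#'   ([SignedAssociationMatrix-class] over the same drug/target universe).
#' @export
readBundle <- function(dir) {
  chem <- readBinaryProfile(file.path(dir, "chemical.tsv"), "chemical")
  targ <- readBinaryProfile(file.path(dir, "target.tsv"), "target")
  labs <- readBinaryProfile(file.path(dir, "side_effects.tsv"),
                            "side_effect")
  rec <- readModeRecords(file.path(dir, "mode_records.tsv"))
  assoc <- buildSignedAssociationMatrix(rec, drugIds = drugIds(targ),
                                        targetIds = featureIds(targ))
  list(chemical = chem, target = targ, labels = labs, assoc = assoc)
}
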