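#' @include AllClasses.R
NULL

## Action-mode vocabulary observed in DrugBank, grouped by the sign the
## mode induces on a drug-target edge.  Activating modes are +1, inhibitory
## modes are -1, modes that do not determine a direction are 0.
.positiveModes <- c(
  "agonist", "partial agonist", "activator", "stimulator", "inducer",
  "positive allosteric modulator", "potentiator", "positive modulator")
.negativeModes <- c(
  "inhibitor", "inhibitory allosteric modulator", "inhibitor competitive",
  "antagonist", "partial antagonist", "negative modulator",
  "inverse agonist", "blocker", "suppressor", "desensitize the target",
  "neutralizer", "reducer")
.neutralModes <- c(
  "antibody", "cofactor", "modulator", "binder", "chaperone", "cleavage",
  "metabolizer", "ligand", "product of", "component of", "chelator",
  "cross-linking/alkylation", "intercalation", "adduct", "acetylation",
  "allosteric modulator")

#' Default action-mode-to-sign map
#'
#' The packaged mapping from lower-cased DrugBank action-mode labels to edge
#' signs: activating modes (agonist, activator, inducer, ...) map to +1,
#' inhibitory modes (antagonist, blocker, suppressor, ...) to -1, and modes
#' that carry no direction (cofactor, binder, ligand, ...) to 0.
#'
#' @return Named integer vector; names are lower-cased mode labels, values
#'   are in \{-1, 0, +1\}.
#' @examples
#' actionModeTable()[c("agonist", "blocker", "cofactor")]
#' @export
actionModeTable <- function() {
  c(stats::setNames(rep(1L, length(.positiveModes)), .positiveModes),
    stats::setNames(rep(-1L, length(.negativeModes)), .negativeModes),
    stats::setNames(rep(0L, length(.neutralModes)), .neutralModes))
}

#' Read an action-mode sign map from JSON
#'
#' The file must be a JSON object mapping mode labels to -1, 0 or +1.  A
#' packaged default reproducing [actionModeTable()] ships at
#' `system.file("extdata", "action_modes.json", package = "rwshin")`.
#'
#' @param path JSON file path.
#' @return Named integer sign map usable as the `map` argument of
#'   [parseModeSign()].
#' @export
readActionModeMap <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(m) || is.null(names(m)) || !all(m %in% -1:1))
    stop("mode map must be a JSON object of label -> sign in {-1, 0, +1}")
  stats::setNames(as.integer(m), tolower(names(m)))
}

#' Map action-mode labels to edge signs
#'
#' Labels are lower-cased before lookup.  Unknown labels map to 0 (not
#' classifiable) with a warning by default; with `strict = TRUE` they raise
#' an error naming the offending labels.
#'
#' @param labels character vector of action-mode labels.
#' @param map named integer sign map, as returned by [actionModeTable()].
#' @param strict logical; error instead of warn on unknown labels.
#' @return Integer vector of signs in \{-1, 0, +1\}, same length as
#'   `labels`.
#' @examples
#' parseModeSign(c("Agonist", "blocker", "cofactor"))
#' @export
parseModeSign <- function(labels, map = actionModeTable(), strict = FALSE) {
  stopifnot(is.numeric(map), !is.null(names(map)), all(map %in% -1:1))
  key <- tolower(as.character(labels))
  sign <- unname(map[key])
  unknown <- unique(key[is.na(sign)])
  if (length(unknown)) {
    if (strict)
      stop("unknown action-mode label(s): ", paste(unknown, collapse = ", "))
    warning("unknown action-mode label(s) mapped to 0: ",
            paste(unknown, collapse = ", "))
    sign[is.na(sign)] <- 0L
  }
  as.integer(sign)
}

#' Read a binary profile TSV
#'
#' Expected layout: a header row `drug_id<TAB>f1<TAB>f2...`, then one row
#' per drug with 0/1 cells.  Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @param kind profile type, one of `"chemical"`, `"side_effect"`,
#'   `"target"`.
#' @return A [BinaryProfileSet-class].
#' @seealso [writeBinaryProfile()]
#' @export
readBinaryProfile <- function(path, kind) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("profile file must have a drug_id column and at least one feature")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate drug id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feat <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!feat %in% c("0", "1"))
  if (length(bad)) {
    r <- (bad[1L] - 1L) %% nrow(feat) + 1L
    c <- (bad[1L] - 1L) %/% nrow(feat) + 1L
    stop(sprintf("non-binary cell '%s' at drug '%s', feature '%s'",
                 feat[bad[1L]], ids[r], colnames(feat)[c]))
  }
  storage.mode(feat) <- "integer"
  rownames(feat) <- ids
  BinaryProfileSet(feat, kind)
}

#' Write a binary profile TSV
#'
#' Inverse of [readBinaryProfile()]: writes the header row of feature ids
#' with a leading `drug_id` column, then one 0/1 row per drug.
#'
#' @param x a [BinaryProfileSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBinaryProfile <- function(x, path) {
  stopifnot(is(x, "BinaryProfileSet"))
  f <- featureMatrix(x)
  tab <- data.frame(drug_id = rownames(f), f, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read long-format drug-target action-mode records
#'
#' @param path TSV with columns `drug_id`, `target_id`, `mode_label`, one
#'   record per row.
#' @return A data.frame with those three character columns.
#' @export
readModeRecords <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("drug_id", "target_id", "mode_label")
  if (!all(need %in% names(tab)))
    stop("mode record file must have columns ", paste(need, collapse = ", "))
  tab[need]
}

#' Write mode records TSV
#'
#' @param records data.frame with columns `drug_id`, `target_id`,
#'   `mode_label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModeRecords <- function(records, path) {
  utils::write.table(records[c("drug_id", "target_id", "mode_label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the signed drug-target association matrix from mode records
#'
#' Each (drug, target, mode) record contributes the sign of its mode; pairs
#' with no record are 0.  When one (drug, target) pair carries several
#' modes whose signs agree (after dropping zeros), the shared sign is kept;
#' a genuine +1/-1 conflict raises an error by default, or is resolved to 0
#' with `conflict = "zero"`.
#'
#' @param records data.frame with columns `drug_id`, `target_id`,
#'   `mode_label`.
#' @param drugIds,targetIds the drug and target universes (character).
#'   Default: the sorted unique ids appearing in `records`.
#' @param map sign map passed to [parseModeSign()].
#' @param strict passed to [parseModeSign()].
#' @param conflict `"error"` (default) or `"zero"`: how to resolve a
#'   (drug, target) pair with both a +1 and a -1 mode.
#' @return A [SignedAssociationMatrix-class].
#' @examples
#' rec <- data.frame(drug_id = c("d1", "d2"), target_id = "t1",
#'                   mode_label = c("agonist", "antagonist"))
#' assocMatrix(buildSignedAssociationMatrix(rec))
#' @export
buildSignedAssociationMatrix <- function(records, drugIds = NULL,
                                         targetIds = NULL,
                                         map = actionModeTable(),
                                         strict = FALSE,
                                         conflict = c("error", "zero")) {
  conflict <- match.arg(conflict)
  if (is.null(drugIds)) drugIds <- sort(unique(records$drug_id))
  if (is.null(targetIds)) targetIds <- sort(unique(records$target_id))
  if (nrow(records)) {
    miss <- setdiff(records$drug_id, drugIds)
    if (length(miss)) stop("record drug(s) not in universe: ",
                           paste(miss, collapse = ", "))
    miss <- setdiff(records$target_id, targetIds)
    if (length(miss)) stop("record target(s) not in universe: ",
                           paste(miss, collapse = ", "))
  }
  A <- matrix(0L, length(drugIds), length(targetIds),
              dimnames = list(drugIds, targetIds))
  if (nrow(records)) {
    sign <- parseModeSign(records$mode_label, map = map, strict = strict)
    key <- paste(records$drug_id, records$target_id, sep = "\r")
    for (k in unique(key)) {
      s <- unique(sign[key == k])
      s <- s[s != 0L]
      if (length(s) > 1L) {
        if (conflict == "error")
          stop("conflicting action-mode signs for pair ",
               sub("\r", " / ", k))
        s <- integer()
      }
      if (!length(s)) s <- 0L
      ij <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      A[ij[1L], ij[2L]] <- s
    }
  }
  SignedAssociationMatrix(A)
}

#' Convert a signed association matrix to long-format mode records
#'
#' Serialization helper: emits one record per nonzero entry using the
#' canonical representative labels `"agonist"` (+1) and `"antagonist"`
#' (-1), so a matrix can round-trip through the record TSV format.
#'
#' @param A a [SignedAssociationMatrix-class].
#' @return data.frame with columns `drug_id`, `target_id`, `mode_label`.
#' @export
assocToModeRecords <- function(A) {
  a <- assocMatrix(A)
  idx <- which(a != 0L, arr.ind = TRUE)
  data.frame(drug_id = rownames(a)[idx[, 1L]],
             target_id = colnames(a)[idx[, 2L]],
             mode_label = ifelse(a[idx] > 0L, "agonist", "antagonist"))
}
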