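#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- classes

#' Binary drug profile set
#'
#' Drugs-by-features 0/1 matrix for one profile type: chemical substructure
#' fingerprints, known side-effect terms, or target proteins.  Row names are
#' drug identifiers, column names are feature identifiers; both must be
#' unique and non-empty.
#'
#' @slot features integer 0/1 matrix with complete dimnames.
#' @slot kind one of `"chemical"`, `"side_effect"`, `"target"`.
#' @export
setClass("BinaryProfileSet",
         representation(features = "matrix", kind = "character"))

.profileKinds <- c("chemical", "side_effect", "target")

setValidity("BinaryProfileSet", function(object) {
  f <- object@features
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% .profileKinds)
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(.profileKinds, collapse = ", ")))
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msgs <- c(msgs, "features must have drug row names and feature column names")
  else {
    if (anyDuplicated(rownames(f)))
      msgs <- c(msgs, "duplicate drug ids")
    if (anyDuplicated(colnames(f)))
      msgs <- c(msgs, "duplicate feature ids")
  }
  if (ncol(f) < 1L)
    msgs <- c(msgs, "profile set must have at least one feature")
  if (!all(f %in% c(0L, 1L)))
    msgs <- c(msgs, "all entries must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BinaryProfileSet
#'
#' @param features 0/1 matrix (numeric or integer) with drug row names and
#'   feature column names.
#' @param kind profile type, one of `"chemical"`, `"side_effect"`,
#'   `"target"`.
#' @return A validated [BinaryProfileSet-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("f1", "f2")))
#' BinaryProfileSet(m, "chemical")
#' @export
BinaryProfileSet <- function(features, kind) {
  storage.mode(features) <- "integer"
  new("BinaryProfileSet", features = features, kind = kind)
}

#' Signed drug-target association matrix
#'
#' Drugs-by-targets matrix A with entries in \{-1, 0, +1\}: +1 when the
#' drug acts on the target in an activating mode (agonist-like), -1 for an
#' inhibitory mode (antagonist-like), 0 for no association or a
#' non-classifiable mode.
#'
#' @slot assoc integer matrix over \{-1, 0, +1\} with drug row names and
#'   target column names.
#' @export
setClass("SignedAssociationMatrix", representation(assoc = "matrix"))

setValidity("SignedAssociationMatrix", function(object) {
  a <- object@assoc
  msgs <- character()
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msgs <- c(msgs, "assoc must have drug row names and target column names")
  else {
    if (anyDuplicated(rownames(a))) msgs <- c(msgs, "duplicate drug ids")
    if (anyDuplicated(colnames(a))) msgs <- c(msgs, "duplicate target ids")
  }
  if (!all(a %in% c(-1L, 0L, 1L)))
    msgs <- c(msgs, "all entries must be -1, 0 or +1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignedAssociationMatrix
#'
#' @param assoc matrix over \{-1, 0, +1\} with drug row names and target
#'   column names.
#' @return A validated [SignedAssociationMatrix-class].
#' @export
SignedAssociationMatrix <- function(assoc) {
  storage.mode(assoc) <- "integer"
  new("SignedAssociationMatrix", assoc = assoc)
}

#' Weighted drug-drug graph, signed or unsigned
#'
#' Undirected graph over the drug universe.  Each unordered node pair is
#' stored at most once (`from` index < `to` index).  Unsigned graphs carry
#' weights in (0, 1]; signed graphs carry weights in \[-1, 1\] excluding 0.
#' Self loops and zero-weight edges are never stored.
#'
#' @slot nodeIds character vector of drug identifiers (the node universe,
#'   including isolated nodes).
#' @slot edges data.frame with integer columns `from`, `to` (indices into
#'   `nodeIds`, `from < to`) and numeric `weight`.
#' @slot signed logical scalar.
#' @export
setClass("DrugGraph",
         representation(nodeIds = "character", edges = "data.frame",
                        signed = "logical"))

setValidity("DrugGraph", function(object) {
  e <- object@edges
  msgs <- character()
  if (!identical(names(e), c("from", "to", "weight")))
    msgs <- c(msgs, "edges must have columns from, to, weight")
  else if (nrow(e)) {
    n <- length(object@nodeIds)
    if (any(e$from < 1L) || any(e$to > n))
      msgs <- c(msgs, "edge endpoints out of range")
    if (any(e$from >= e$to))
      msgs <- c(msgs, "edges must satisfy from < to (no self-loops, one row per pair)")
    if (anyDuplicated(e[c("from", "to")]))
      msgs <- c(msgs, "duplicate edges")
    if (object@signed) {
      if (any(e$weight == 0) || any(abs(e$weight) > 1))
        msgs <- c(msgs, "signed weights must lie in [-1, 1] and be nonzero")
    } else if (any(e$weight <= 0) || any(e$weight > 1))
      msgs <- c(msgs, "unsigned weights must lie in (0, 1]")
  }
  if (anyDuplicated(object@nodeIds))
    msgs <- c(msgs, "duplicate node ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DrugGraph
#'
#' @param nodeIds character vector of drug identifiers.
#' @param edges data.frame with columns `from`, `to` (drug identifiers or
#'   integer indices into `nodeIds`) and `weight`; one row per unordered
#'   pair.
#' @param signed logical; `TRUE` for a signed graph.
#' @return A validated [DrugGraph-class].
#' @examples
#' DrugGraph(c("a", "b", "c"),
#'           data.frame(from = "a", to = "b", weight = 0.5),
#'           signed = FALSE)
#' @export
DrugGraph <- function(nodeIds,
                      edges = data.frame(from = integer(), to = integer(),
                                         weight = numeric()),
                      signed = FALSE) {
  if (nrow(edges)) {
    if (is.character(edges$from) || is.factor(edges$from)) {
      i <- match(as.character(edges$from), nodeIds)
      j <- match(as.character(edges$to), nodeIds)
      if (anyNA(i) || anyNA(j))
        stop("edge endpoints not in nodeIds: ",
             paste(unique(c(edges$from[is.na(i)], edges$to[is.na(j)])),
                   collapse = ", "))
    } else {
      i <- as.integer(edges$from); j <- as.integer(edges$to)
    }
    lo <- pmin(i, j); hi <- pmax(i, j)
    edges <- data.frame(from = lo, to = hi, weight = as.numeric(edges$weight))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  }
  new("DrugGraph", nodeIds = as.character(nodeIds), edges = edges,
      signed = isTRUE(signed))
}

#' Signed drug heterogeneous information network
#'
#' Bundle of the four drug-drug subnetworks over one shared drug universe:
#' `chemical`, `side_effect` and `target` (unsigned Jaccard graphs) plus
#' `signed_target` (the signed action-mode graph).  The signed subnetwork
#' may be edgeless, which degenerates the method to its unsigned ablation.
#'
#' @slot subnetworks named list of four [DrugGraph-class] objects.
#' @export
setClass("DrugHIN", representation(subnetworks = "list"))

.hinNames <- c("chemical", "side_effect", "target", "signed_target")

setValidity("DrugHIN", function(object) {
  sn <- object@subnetworks
  msgs <- character()
  if (!identical(sort(names(sn)), sort(.hinNames)))
    msgs <- c(msgs, sprintf("subnetworks must be named %s",
                            paste(.hinNames, collapse = ", ")))
  else {
    if (!all(vapply(sn, is, logical(1), "DrugGraph")))
      msgs <- c(msgs, "all subnetworks must be DrugGraph objects")
    else {
      ref <- sn[[1L]]@nodeIds
      for (nm in names(sn))
        if (!identical(sn[[nm]]@nodeIds, ref)) {
          d <- union(setdiff(sn[[nm]]@nodeIds, ref), setdiff(ref, sn[[nm]]@nodeIds))
          msgs <- c(msgs, sprintf("node universe mismatch in '%s': %s", nm,
                                  paste(d, collapse = ", ")))
        }
      if (!sn$signed_target@signed)
        msgs <- c(msgs, "signed_target must be a signed graph")
      for (nm in setdiff(.hinNames, "signed_target"))
        if (sn[[nm]]@signed)
          msgs <- c(msgs, sprintf("'%s' must be unsigned", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Corpus of random-walk drug sequences
#'
#' @slot walkList list of character vectors, one drug-id sequence per walk.
#' @slot source character vector tagging each walk with the subnetwork it
#'   was sampled from.
#' @export
setClass("WalkCorpus",
         representation(walkList = "list", source = "character"))

setValidity("WalkCorpus", function(object) {
  msgs <- character()
  if (length(object@walkList) != length(object@source))
    msgs <- c(msgs, "one source tag per walk required")
  if (length(object@walkList) &&
      any(lengths(object@walkList) < 1L))
    msgs <- c(msgs, "walks must have length >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WalkCorpus
#'
#' @param walkList list of character vectors (drug-id sequences).
#' @param source character vector of per-walk subnetwork tags (recycled if
#'   scalar).
#' @return A validated [WalkCorpus-class].
#' @export
WalkCorpus <- function(walkList, source = "unknown") {
  if (length(source) == 1L) source <- rep(source, length(walkList))
  new("WalkCorpus", walkList = walkList, source = as.character(source))
}

#' Drug embedding set
#'
#' Map from drug identifier to a d-dimensional real vector, plus the
#' training metadata needed to reproduce it.
#'
#' @slot vectors numeric matrix, drugs in rows (rownames are drug ids), d
#'   columns.
#' @slot meta list of training metadata (window, epochs, negative samples,
#'   learning rate, seed, final average loss).
#' @export
setClass("EmbeddingSet", representation(vectors = "matrix", meta = "list"))

setValidity("EmbeddingSet", function(object) {
  v <- object@vectors
  msgs <- character()
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "vectors must have unique drug rownames")
  if (!all(is.finite(v)))
    msgs <- c(msgs, "all embedding entries must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EmbeddingSet
#'
#' @param vectors numeric matrix with drug rownames.
#' @param meta list of training metadata.
#' @return A validated [EmbeddingSet-class].
#' @export
EmbeddingSet <- function(vectors, meta = list()) {
  new("EmbeddingSet", vectors = vectors, meta = meta)
}

## -------------------------------------------------------------- accessors

#' @rdname drugIds
#' @export
setMethod("drugIds", "BinaryProfileSet", function(x) rownames(x@features))
#' @rdname drugIds
#' @export
setMethod("drugIds", "SignedAssociationMatrix", function(x) rownames(x@assoc))
#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugGraph", function(x) x@nodeIds)
#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugHIN", function(x) x@subnetworks[[1L]]@nodeIds)
#' @rdname drugIds
#' @export
setMethod("drugIds", "EmbeddingSet", function(x) rownames(x@vectors))

#' @rdname featureIds
#' @export
setMethod("featureIds", "BinaryProfileSet", function(x) colnames(x@features))

#' @rdname profileKind
#' @export
setMethod("profileKind", "BinaryProfileSet", function(x) x@kind)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "BinaryProfileSet", function(x) x@features)

#' @rdname assocMatrix
#' @export
setMethod("assocMatrix", "SignedAssociationMatrix", function(x) x@assoc)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "DrugGraph", function(x) x@nodeIds)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "DrugGraph", function(x) {
  e <- x@edges
  data.frame(from = x@nodeIds[e$from], to = x@nodeIds[e$to],
             weight = e$weight)
})

#' @rdname isSigned
#' @export
setMethod("isSigned", "DrugGraph", function(x) x@signed)

#' @rdname subnetwork
#' @export
setMethod("subnetwork", "DrugHIN", function(x, name) {
  name <- match.arg(name, .hinNames)
  x@subnetworks[[name]]
})

#' @rdname walks
#' @export
setMethod("walks", "WalkCorpus", function(x) x@walkList)

#' @rdname walkSource
#' @export
setMethod("walkSource", "WalkCorpus", function(x) x@source)

#' @rdname embeddingMatrix
#' @export
setMethod("embeddingMatrix", "EmbeddingSet", function(x) x@vectors)

#' @rdname embeddingDim
#' @export
setMethod("embeddingDim", "EmbeddingSet", function(x) ncol(x@vectors))

## ------------------------------------------------------------------- show

setMethod("show", "BinaryProfileSet", function(object) {
  f <- object@features
  cat(sprintf("BinaryProfileSet [%s]: %d drugs x %d features, density %.3f\n",
              object@kind, nrow(f), ncol(f), mean(f)))
})

setMethod("show", "SignedAssociationMatrix", function(object) {
  a <- object@assoc
  cat(sprintf(
    "SignedAssociationMatrix: %d drugs x %d targets (+%d / -%d nonzero)\n",
    nrow(a), ncol(a), sum(a > 0), sum(a < 0)))
})

setMethod("show", "DrugGraph", function(object) {
  e <- object@edges
  if (object@signed)
    cat(sprintf("DrugGraph (signed): %d nodes, %d edges (+%d / -%d)\n",
                length(object@nodeIds), nrow(e), sum(e$weight > 0),
                sum(e$weight < 0)))
  else
    cat(sprintf("DrugGraph (unsigned): %d nodes, %d edges\n",
                length(object@nodeIds), nrow(e)))
})

setMethod("show", "DrugHIN", function(object) {
  cat(sprintf("DrugHIN: %d drugs\n", length(drugIds(object))))
  for (nm in .hinNames)
    cat("  ", nm, ": ", nrow(object@subnetworks[[nm]]@edges), " edges\n",
        sep = "")
})

setMethod("show", "WalkCorpus", function(object) {
  cat(sprintf("WalkCorpus: %d walks from %d subnetwork(s), %d tokens\n",
              length(object@walkList), length(unique(object@source)),
              sum(lengths(object@walkList))))
})

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d drugs, d = %d\n", nrow(object@vectors),
              ncol(object@vectors)))
})
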