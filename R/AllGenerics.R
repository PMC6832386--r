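#' @include rwshin-package.R
NULL

#' Drug identifiers of an object
#'
#' Every container in the package is anchored to an ordered drug universe;
#' `drugIds()` returns it as a character vector.
#'
#' @param x a `BinaryProfileSet`, `SignedAssociationMatrix`, `DrugGraph`,
#'   `DrugHIN` or `EmbeddingSet`.
#' @return Character vector of drug identifiers, in storage order.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' Feature identifiers of a binary profile set
#'
#' @param x a `BinaryProfileSet`.
#' @return Character vector of feature (substructure bit, side-effect term,
#'   or target) identifiers.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Profile kind of a binary profile set
#'
#' @param x a `BinaryProfileSet`.
#' @return One of `"chemical"`, `"side_effect"`, `"target"`.
#' @export
setGeneric("profileKind", function(x) standardGeneric("profileKind"))

#' Binary feature matrix of a profile set
#'
#' @param x a `BinaryProfileSet`.
#' @return Integer 0/1 matrix, drugs in rows, features in columns, with
#'   dimnames.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Signed association matrix entries
#'
#' @param x a `SignedAssociationMatrix`.
#' @return Integer matrix over \{-1, 0, +1\}, drugs in rows, targets in
#'   columns.
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' Node identifiers of a drug graph
#'
#' @param x a `DrugGraph`.
#' @return Character vector of node (drug) identifiers.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Edge table of a drug graph
#'
#' @param x a `DrugGraph`.
#' @return A `data.frame` with columns `from`, `to` (drug identifiers,
#'   `from < to` lexicographic storage is not guaranteed but each unordered
#'   pair appears once) and `weight`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Is a drug graph signed?
#'
#' @param x a `DrugGraph`.
#' @return `TRUE` for a signed graph (weights in \[-1, 1\] excluding 0),
#'   `FALSE` for a nonnegative-weight graph.
#' @export
setGeneric("isSigned", function(x) standardGeneric("isSigned"))

#' Extract one subnetwork from a drug HIN
#'
#' @param x a `DrugHIN`.
#' @param name one of `"chemical"`, `"side_effect"`, `"target"`,
#'   `"signed_target"`.
#' @return The named `DrugGraph`.
#' @export
setGeneric("subnetwork", function(x, name) standardGeneric("subnetwork"))

#' Walks stored in a corpus
#'
#' @param x a `WalkCorpus`.
#' @return List of character vectors, one drug-id sequence per walk.
#' @export
setGeneric("walks", function(x) standardGeneric("walks"))

#' Per-walk provenance tags of a corpus
#'
#' @param x a `WalkCorpus`.
#' @return Character vector naming the source subnetwork of each walk.
#' @export
setGeneric("walkSource", function(x) standardGeneric("walkSource"))

#' Embedding matrix of an embedding set
#'
#' @param x an `EmbeddingSet`.
#' @return Numeric matrix, one row per drug (rownames are drug ids), `d`
#'   columns.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' Embedding dimension
#'
#' @param x an `EmbeddingSet`.
#' @return Integer embedding dimension `d`.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
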