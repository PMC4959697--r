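#' Background position space
#'
#' The background set S of all candidate neural positions (voxels or
#' parcels) considered in the study, against which enrichment is measured.
#' Positions are identified by unique positive integers; MNI millimetre
#' coordinates may be attached for visualization export.
#'
#' @param ids integer vector of unique position identifiers.
#' @param coords optional numeric matrix with one row per position and three
#'   columns (x, y, z in MNI mm), in the same order as `ids`.
#' @return an object of class `position_space` with elements `ids`, `coords`
#'   and `M` (the background size).
#' @export
position_space <- function(ids, coords = NULL) {
  ids <- as.integer(ids)
  if (length(ids) < 1L) stop("background must contain at least one position",
                             call. = FALSE)
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("position identifiers must be unique non-missing integers",
         call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (!is.numeric(coords) || ncol(coords) != 3L ||
        nrow(coords) != length(ids)) {
      stop("coords must be a numeric matrix with one (x, y, z) row per position",
           call. = FALSE)
    }
    rownames(coords) <- ids
  }
  structure(list(ids = ids, coords = coords, M = length(ids)),
            class = "position_space")
}

#' @export
print.position_space <- function(x, ...) {
  cat("<position_space> M =", x$M, "positions",
      if (is.null(x$coords)) "(no coordinates)" else "(with MNI coordinates)",
      "\n")
  invisible(x)
}

#' Neural annotation: named classes of positions
#'
#' Maps named annotation classes (functional networks, anatomic structures,
#' ...) to subsets of a position space. Classes may overlap for position
#' group analysis; connection group analysis requires pairwise-disjoint
#' classes and enforces this at run time.
#'
#' @param classes named list of integer vectors of position identifiers.
#' @return an object of class `neuro_annotation`.
#' @export
neuro_annotation <- function(classes) {
  if (!is.list(classes) || length(classes) == 0L ||
      is.null(names(classes)) || any(names(classes) == "")) {
    stop("annotation must be a non-empty named list of id vectors",
         call. = FALSE)
  }
  if (anyDuplicated(names(classes))) {
    stop("duplicate class names in annotation", call. = FALSE)
  }
  classes <- lapply(classes, function(v) sort(unique(as.integer(v))))
  structure(list(classes = classes), class = "neuro_annotation")
}

#' @export
print.neuro_annotation <- function(x, ...) {
  sizes <- vapply(x$classes, length, integer(1))
  cat("<neuro_annotation>", length(sizes), "classes:",
      paste0(names(sizes), " (", sizes, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Restrict an annotation to a background position space
#'
#' Drops annotation members that are not in the background (so every class
#' capacity is `K = |B intersect S|`) and removes classes left empty. The
#' number of dropped ids is reported via a message.
#'
#' @param annotation a [neuro_annotation()].
#' @param space a [position_space()].
#' @param drop_empty drop classes with no members in the background.
#' @return a `neuro_annotation` whose classes are subsets of `space$ids`.
#' @export
restrict_annotation <- function(annotation, space, drop_empty = TRUE) {
  stopifnot(inherits(annotation, "neuro_annotation"),
            inherits(space, "position_space"))
  before <- sum(vapply(annotation$classes, length, integer(1)))
  classes <- lapply(annotation$classes, function(v) v[v %in% space$ids])
  after <- sum(vapply(classes, length, integer(1)))
  if (after < before) {
    message(before - after,
            " annotated position(s) outside the background were dropped")
  }
  if (drop_empty) {
    empty <- vapply(classes, length, integer(1)) == 0L
    if (any(empty)) {
      message("skipping ", sum(empty), " class(es) empty in the background: ",
              paste(names(classes)[empty], collapse = ", "))
      classes <- classes[!empty]
    }
  }
  if (length(classes) == 0L) {
    stop("no usable annotation classes after background restriction",
         call. = FALSE)
  }
  neuro_annotation(classes)
}

#' Identified groups of neural positions
#'
#' One or more sets of positions identified by a study (for example voxels
#' whose activity tracks a condition), keyed by group identifier.
#'
#' @param groups named list of integer vectors of position identifiers.
#' @return an object of class `position_groups`.
#' @export
position_groups <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups))) {
    stop("no groups found", call. = FALSE)
  }
  groups <- lapply(groups, function(v) sort(unique(as.integer(v))))
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("groups must be non-empty", call. = FALSE)
  }
  structure(list(groups = groups), class = "position_groups")
}

#' @export
print.position_groups <- function(x, ...) {
  sizes <- vapply(x$groups, length, integer(1))
  cat("<position_groups>", length(sizes), "group(s):",
      paste0(names(sizes), " (N=", sizes, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Identified groups of neural connections
#'
#' Sets of unordered position pairs (graph edges), keyed by group
#' identifier. Each group defines a simple undirected graph over the
#' background positions: pairs are normalized to (smaller id, larger id),
#' duplicates are collapsed with a warning, and self-pairs are rejected.
#'
#' @param groups named list of two-column integer matrices (one edge per
#'   row) or of data frames with two columns.
#' @return an object of class `connection_groups`.
#' @export
connection_groups <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups))) {
    stop("no groups found", call. = FALSE)
  }
  groups <- lapply(groups, normalize_pairs)
  structure(list(groups = groups), class = "connection_groups")
}

#' @export
print.connection_groups <- function(x, ...) {
  sizes <- vapply(x$groups, nrow, integer(1))
  cat("<connection_groups>", length(sizes), "group(s):",
      paste0(names(sizes), " (", sizes, " edges)", collapse = ", "), "\n")
  invisible(x)
}

# canonicalize an edge list: integer, i < j, no self-pairs, unique rows
normalize_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L || nrow(pairs) < 1L || anyNA(pairs)) {
    stop("connections must be a non-empty two-column integer table",
         call. = FALSE)
  }
  if (any(pairs[, 1L] == pairs[, 2L])) {
    stop("self-connection: a position cannot be paired with itself",
         call. = FALSE)
  }
  swapped <- pairs[, 1L] > pairs[, 2L]
  pairs[swapped, ] <- pairs[swapped, c(2L, 1L), drop = FALSE]
  key <- paste(pairs[, 1L], pairs[, 2L])
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate connection(s) collapsed",
            call. = FALSE)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

# shared guard: every id used by groups must exist in the background
check_ids_in_space <- function(ids, space, what = "position") {
  missing <- setdiff(ids, space$ids)
  if (length(missing)) {
    stop(what, " identifier(s) absent from the background: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...", call. = FALSE)
  }
  invisible(TRUE)
}
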