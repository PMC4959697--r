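# Readers and writers for the external formats: tabular/coordinate text
# files, NIFTI group volumes, BrainNet Viewer exports and the TSV report.
#
# Position id convention: ids are 1-based everywhere. For coordinate files
# the line number is the id. For NIFTI volumes the id is the 1-based
# column-major linear index of the voxel in the full volume, so ids agree
# across any set of volumes that share the grid dimensions.

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(data.frame())
  dat <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      colClasses = "numeric"),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  dat
}

#' Read the background position set
#'
#' The background defines the sampling space for all enrichment tests and
#' should contain every position considered by the upstream analysis.
#' Three formats are supported:
#' \describe{
#'   \item{`coords`}{text file with one MNI coordinate triple (x y z, mm)
#'     per line; the 1-based line number becomes the position id.}
#'   \item{`tabular`}{text file with one position id per line, or four
#'     columns `id x y z`. Also used for numeric matrices exported from
#'     MATLAB as text.}
#'   \item{`nifti`}{NIFTI-1 volume; every voxel with a nonzero value is a
#'     background position, with the 1-based column-major linear voxel index
#'     as id and mm coordinates from the affine.}
#' }
#'
#' @param path input file.
#' @param format one of `"coords"`, `"tabular"`, `"nifti"`.
#' @return a [position_space()].
#' @export
read_background <- function(path, format = c("coords", "tabular", "nifti")) {
  format <- match.arg(format)
  if (format == "nifti") {
    img <- read_nifti(path)
    keep <- which(img$data != 0)            # column-major linear indices
    if (length(keep) == 0L) stop("background mask is empty", call. = FALSE)
    coords <- voxel_mm(keep, dim(img$data), img$affine)
    return(position_space(keep, coords))
  }
  dat <- read_table_file(path)
  if (format == "coords") {
    if (ncol(dat) != 3L) {
      stop("coordinate background must have exactly 3 columns (x y z)",
           call. = FALSE)
    }
    if (anyDuplicated(dat)) {
      warning("duplicate coordinate lines treated as distinct positions",
              call. = FALSE)
    }
    return(position_space(seq_len(nrow(dat)), as.matrix(dat)))
  }
  if (ncol(dat) == 1L) return(position_space(dat[[1L]]))
  if (ncol(dat) == 4L) {
    return(position_space(dat[[1L]], as.matrix(dat[, 2:4])))
  }
  stop("tabular background must have 1 (id) or 4 (id x y z) columns",
       call. = FALSE)
}

#' Read identified position groups
#'
#' @param path input file.
#' @param space the background [position_space()]; every position id in the
#'   file must belong to it.
#' @param format `"tabular"`/`"matrix"`: two columns, `position_id
#'   group_id`; `"nifti"`: a volume with a positive integer group label at
#'   each in-group voxel (0 = not in any group). The background is always a
#'   separate input, never inferred from the group volume.
#' @return a [position_groups()].
#' @export
read_position_groups <- function(path, space,
                                 format = c("tabular", "nifti", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(space, "position_space"))
  if (format == "nifti") {
    img <- read_nifti(path)
    vals <- img$data
    idx <- which(vals > 0)
    if (length(idx) == 0L) stop("no groups found", call. = FALSE)
    labels <- vals[idx]
    if (any(labels != round(labels))) {
      stop("group volume contains non-integer labels", call. = FALSE)
    }
    check_ids_in_space(idx, space)
    groups <- split(idx, as.integer(labels))
    return(position_groups(groups))
  }
  dat <- read_table_file(path)
  if (nrow(dat) == 0L || ncol(dat) != 2L) {
    stop("no groups found: expected two columns (position_id group_id)",
         call. = FALSE)
  }
  if (any(dat != round(dat))) {
    stop("group file contains non-integer labels", call. = FALSE)
  }
  check_ids_in_space(dat[[1L]], space)
  position_groups(split(as.integer(dat[[1L]]), as.integer(dat[[2L]])))
}

#' Read identified connection groups
#'
#' Three numeric columns per row: two position identifiers followed by the
#' group identifier. Pairs are normalized to unordered form; duplicated
#' pairs (e.g. both orientations of the same connection) are collapsed with
#' a warning; self-pairs are an error.
#'
#' @param path input file.
#' @param space the background [position_space()].
#' @param format `"tabular"` or `"matrix"` (text export of a numeric
#'   matrix); identical semantics.
#' @return a [connection_groups()].
#' @export
read_connection_groups <- function(path, space,
                                   format = c("tabular", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(space, "position_space"))
  dat <- read_table_file(path)
  if (nrow(dat) == 0L || ncol(dat) != 3L) {
    stop("no groups found: expected three columns (id id group_id)",
         call. = FALSE)
  }
  check_ids_in_space(c(dat[[1L]], dat[[2L]]), space)
  pairs <- split(seq_len(nrow(dat)), as.integer(dat[[3L]]))
  groups <- lapply(pairs, function(rows)
    as.matrix(dat[rows, 1:2, drop = FALSE]))
  connection_groups(groups)
}

#' Read a neural annotation
#'
#' @param path input file. Tabular format: two columns, `position_id
#'   class_label`, where the label is a class name or an integer code;
#'   NIFTI format: a volume whose voxel values are integer class codes
#'   (0 = unannotated).
#' @param space the background [position_space()]; annotated positions
#'   outside it are dropped (with a message), so class capacities are always
#'   measured inside the background.
#' @param format `"tabular"` or `"nifti"`.
#' @param legend optional path to a two-column text file mapping integer
#'   codes to class names.
#' @return a [neuro_annotation()] restricted to the background.
#' @export
read_annotation <- function(path, space, format = c("tabular", "nifti"),
                            legend = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(space, "position_space"))
  legend_map <- NULL
  if (!is.null(legend)) {
    ldat <- utils::read.table(legend, header = FALSE,
                              colClasses = c("integer", "character"))
    legend_map <- stats::setNames(ldat[[2L]], ldat[[1L]])
  }
  if (format == "nifti") {
    img <- read_nifti(path)
    idx <- which(img$data > 0)
    if (length(idx) == 0L) stop("empty annotation", call. = FALSE)
    labels <- as.integer(img$data[idx])
    ids <- idx
  } else {
    dat <- tryCatch(
      utils::read.table(path, header = FALSE,
                        colClasses = c("integer", "character")),
      error = function(e) stop("cannot parse '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(dat) == 0L || ncol(dat) != 2L) {
      stop("empty annotation", call. = FALSE)
    }
    ids <- dat[[1L]]
    labels <- dat[[2L]]
  }
  if (!is.null(legend_map)) {
    unknown <- setdiff(unique(as.character(labels)), names(legend_map))
    if (length(unknown)) {
      stop("legend label missing for code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    labels <- legend_map[as.character(labels)]
  }
  ann <- neuro_annotation(split(ids, labels))
  restrict_annotation(ann, space)
}

#' Write an enrichment report as TSV
#'
#' One row per tested (group, class or class-pair) combination with the
#' full test parameters for auditability, sorted by q-value.
#'
#' @param results an enrichment result data frame, as returned by
#'   [run_position_analysis()] or [run_connection_analysis()].
#' @param path output file.
#' @param alpha optional filter: keep only rows with `q <= alpha`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, alpha = NULL) {
  stopifnot(is.data.frame(results))
  out <- results[order(results$q, results$p), , drop = FALSE]
  if (!is.null(alpha)) out <- out[out$q <= alpha, , drop = FALSE]
  utils::write.table(format(out, digits = 6, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export significant enrichments for BrainNet Viewer
#'
#' Writes one `.node` file per significant result listing the positions
#' that are both in the tested group and in the enriched class (columns:
#' x y z color size label), and for connection results additionally a
#' square 0/1 `.edge` matrix over those positions. Files are named
#' `<prefix>_<group>_<class>.node/.edge`.
#'
#' @param results enrichment result data frame.
#' @param space [position_space()] carrying MNI coordinates.
#' @param groups the [position_groups()] or [connection_groups()] that were
#'   tested.
#' @param annotation the [neuro_annotation()] that was tested.
#' @param out_prefix path prefix for output files.
#' @param alpha significance level applied to q-values (default 0.05).
#' @return character vector of files written (empty when nothing is
#'   significant), invisibly.
#' @export
export_brainnet <- function(results, space, groups, annotation, out_prefix,
                            alpha = 0.05) {
  stopifnot(inherits(space, "position_space"))
  if (is.null(space$coords)) {
    stop("BrainNet export requires MNI coordinates in the background",
         call. = FALSE)
  }
  sig <- results[results$q <= alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    message("no significant results at alpha = ", alpha, "; nothing exported")
    return(invisible(character(0)))
  }
  classes <- restrict_annotation(annotation, space)$classes
  class_color <- stats::setNames(seq_along(classes), names(classes))
  written <- character(0)
  coord_of <- function(ids) space$coords[match(ids, space$ids), , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    grp <- as.character(sig$group[r])
    cls <- as.character(sig$class[r])
    safe <- gsub("[^A-Za-z0-9_.-]", "_", paste(grp, cls, sep = "_"))
    if (inherits(groups, "position_groups")) {
      members <- intersect(groups$groups[[grp]], classes[[cls]])
      if (length(members) == 0L) next
      node <- cbind(coord_of(members), class_color[[cls]], 1, members)
      node_path <- paste0(out_prefix, "_", safe, ".node")
      utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      written <- c(written, node_path)
    } else {
      pair <- strsplit(cls, "-", fixed = TRUE)[[1L]]
      C <- classes[[pair[1L]]]
      D <- classes[[pair[2L]]]
      edges <- groups$groups[[grp]]
      hit <- edge_in_class_pair(edges, C, D)
      sub <- edges[hit, , drop = FALSE]
      if (nrow(sub) == 0L) next
      nodes <- sort(unique(c(sub)))
      color <- ifelse(nodes %in% C, class_color[[pair[1L]]],
                      class_color[[pair[2L]]])
      node <- cbind(coord_of(nodes), color, 1, nodes)
      adj <- matrix(0L, length(nodes), length(nodes))
      ii <- match(sub[, 1L], nodes); jj <- match(sub[, 2L], nodes)
      adj[cbind(ii, jj)] <- 1L
      adj[cbind(jj, ii)] <- 1L
      node_path <- paste0(out_prefix, "_", safe, ".node")
      edge_path <- paste0(out_prefix, "_", safe, ".edge")
      utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      utils::write.table(adj, edge_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      written <- c(written, node_path, edge_path)
    }
  }
  invisible(written)
}

# mm coordinates of 1-based column-major voxel indices under an affine
voxel_mm <- function(lin_idx, dims, affine) {
  idx0 <- arrayInd(lin_idx, dims) - 1L
  t(affine[1:3, 1:3] %*% t(idx0) + affine[1:3, 4L])
}
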