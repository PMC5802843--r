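## gene columns of a cell-profile table
profile_genes <- function(profiles, genes = NULL) {
  if (!is.null(genes)) return(genes)
  g <- attr(profiles, "genes")
  if (is.null(g)) {
    meta <- c("cell_id", "fov", "x", "y", "area_px", "nuc_area_px",
              "nuc_perimeter_px", "nuc_eccentricity")
    g <- setdiff(names(profiles), meta)
  }
  g
}

#' Normalize per-gene intensities onto a 0:10 scale
#'
#' For each gene, every cell's mean intensity is divided by the largest
#' value observed in any cell over all fields of view and multiplied by
#' ten, so the brightest cell maps to exactly 10.
#'
#' @param profiles cell-profile data.frame (or plain cells x genes matrix).
#' @param genes gene columns to normalize; defaults to the table's recorded
#'   gene set (or all columns of a matrix).
#' @return the input with gene columns normalized; attribute `transform`
#'   set to `"normalized"`.
#' @export
normalize_profiles <- function(profiles, genes = NULL) {
  if (is.matrix(profiles)) {
    mx <- apply(profiles, 2L, max)
    if (any(mx <= 0)) {
      stop("all-zero gene(s): ",
           paste(colnames(profiles)[mx <= 0], collapse = ", "))
    }
    out <- sweep(profiles, 2L, mx, "/") * 10
    attr(out, "transform") <- "normalized"
    return(out)
  }
  genes <- profile_genes(profiles, genes)
  mx <- vapply(profiles[genes], max, numeric(1))
  if (any(mx <= 0)) {
    stop("all-zero gene(s): ", paste(genes[mx <= 0], collapse = ", "))
  }
  for (g in genes) profiles[[g]] <- 10 * profiles[[g]] / mx[[g]]
  attr(profiles, "genes") <- genes
  attr(profiles, "transform") <- "normalized"
  profiles
}

#' Log-transform normalized intensities onto a -1:1 scale
#'
#' Applies `log10(0.1 + x)` to 0:10-normalized values, mapping 0 to -1 and
#' 10 to `log10(10.1)` (about 1.004). Values outside `[0, 10]` are
#' rejected.
#'
#' @inheritParams normalize_profiles
#' @return the input with gene columns transformed; attribute `transform`
#'   set to `"log"`.
#' @export
log_transform_profiles <- function(profiles, genes = NULL) {
  tol <- 1e-9
  trans <- function(x) {
    if (any(x < -tol | x > 10 + tol)) {
      stop("values outside [0, 10]; normalize first")
    }
    log10(0.1 + pmin(pmax(x, 0), 10))
  }
  if (is.matrix(profiles)) {
    out <- apply(profiles, 2L, trans)
    dim(out) <- dim(profiles); dimnames(out) <- dimnames(profiles)
    attr(out, "transform") <- "log"
    return(out)
  }
  genes <- profile_genes(profiles, genes)
  for (g in genes) profiles[[g]] <- trans(profiles[[g]])
  attr(profiles, "genes") <- genes
  attr(profiles, "transform") <- "log"
  profiles
}

#' Classify cells by k-means in log-expression space
#'
#' Partitions cells into `k` molecularly distinct classes by k-means on
#' the log-transformed expression profiles (Euclidean distance, multiple
#' random restarts, fixed seed for reproducibility). No spatial
#' information enters the clustering.
#'
#' @param profiles cell-profile table (normalized + log-transformed) or a
#'   cells x genes matrix in log space.
#' @param k number of classes.
#' @param seed random seed; the same seed reproduces the assignment
#'   exactly.
#' @param n_init number of random restarts.
#' @param genes gene columns to cluster on.
#' @return an object of class `plish_classification`: `cluster` (per-cell
#'   id 1..k), `centroids` (k x genes matrix, the centroid heat-map
#'   table), `cell_id`, `k`, `tot_withinss`.
#' @export
kmeans_classify <- function(profiles, k = 10L, seed = 0L, n_init = 50L,
                            genes = NULL) {
  m <- as_gene_matrix(profiles, genes)
  if (k > nrow(m)) stop("k exceeds the number of cells")
  km <- with_seed(seed, kmeans(m, centers = k, nstart = n_init,
                               iter.max = 100L))
  structure(list(
    cluster = unname(km$cluster),
    centroids = km$centers,
    cell_id = if (is.data.frame(profiles) && !is.null(profiles$cell_id))
      profiles$cell_id else seq_len(nrow(m)),
    k = k, seed = seed, tot_withinss = km$tot.withinss
  ), class = "plish_classification")
}

as_gene_matrix <- function(profiles, genes = NULL) {
  if (is.matrix(profiles)) return(profiles)
  genes <- profile_genes(profiles, genes)
  as.matrix(profiles[genes])
}

#' @export
print.plish_classification <- function(x, ...) {
  cat(sprintf("k-means cell classification: %d cells, k = %d\n",
              length(x$cluster), x$k))
  tab <- table(x$cluster)
  cat("  cluster sizes:", paste(sprintf("%s:%d", names(tab), tab),
                                collapse = " "), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Hierarchical clustering of single-cell profiles
#'
#' Agglomerative clustering of the log-transformed expression profiles
#' (default Euclidean distance, average linkage), returning the dendrogram
#' and a leaf order for heat-map display.
#'
#' @inheritParams kmeans_classify
#' @param method linkage passed to [stats::hclust()].
#' @param metric distance passed to [stats::dist()].
#' @return list with `tree` (an `hclust`) and `order` (leaf order).
#' @export
hierarchical_cluster <- function(profiles, method = "average",
                                 metric = "euclidean", genes = NULL) {
  m <- as_gene_matrix(profiles, genes)
  if (nrow(m) < 2L) stop("need at least 2 cells")
  tree <- hclust(dist(m, method = metric), method = method)
  list(tree = tree, order = tree$order)
}

#' Two-dimensional t-SNE embedding of cell profiles
#'
#' Visualization-only embedding of the log-expression profiles; it never
#' feeds classification. Deterministic for a fixed seed.
#'
#' @inheritParams kmeans_classify
#' @param perplexity t-SNE perplexity; requires `cells > 3 * perplexity`.
#' @param ... passed to [Rtsne::Rtsne()].
#' @return cells x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(profiles, seed = 0L, perplexity = 30, genes = NULL,
                       ...) {
  m <- as_gene_matrix(profiles, genes)
  if (nrow(m) <= 3 * perplexity) {
    stop("perplexity too large: need cells > 3 * perplexity")
  }
  fit <- with_seed(seed, Rtsne::Rtsne(m, dims = 2L, perplexity = perplexity,
                                      check_duplicates = FALSE,
                                      pca = FALSE, ...))
  out <- fit$Y
  colnames(out) <- c("tsne1", "tsne2")
  out
}

#' Label clusters from marker-gene rules
#'
#' Assigns a biological label to each cluster centroid from a rule table.
#' A rule fires when every listed marker gene exceeds its threshold in the
#' centroid. Rules are evaluated in order of `precedence` (1 = highest),
#' so a double-positive rule (e.g. Sftpc+Scgb1a1 -> BASC) takes precedence
#' over the single-positive rules it overlaps (Sftpc -> AT2,
#' Scgb1a1 -> Club). Two rules matching one centroid at equal precedence
#' is an error; a centroid matching no rule is labeled `"other"`.
#'
#' @param centroids k x genes centroid matrix
#'   (`classification$centroids`).
#' @param rules data.frame with columns `label`, `markers`
#'   (comma-separated gene names), `threshold`, `precedence`.
#' @param classification optional `plish_classification` to annotate
#'   in-place (returned with `$labels` set).
#' @return character vector of per-cluster labels (or the annotated
#'   classification).
#' @export
assign_cell_type <- function(centroids, rules, classification = NULL) {
  stopifnot(all(c("label", "markers", "threshold", "precedence") %in%
                  names(rules)))
  labels <- rep("other", nrow(centroids))
  for (prec in sort(unique(rules$precedence))) {
    level <- rules[rules$precedence == prec, , drop = FALSE]
    for (ci in seq_len(nrow(centroids))) {
      if (labels[ci] != "other") next      # resolved at higher precedence
      hits <- character(0)
      for (ri in seq_len(nrow(level))) {
        markers <- trimws(strsplit(level$markers[ri], ",")[[1L]])
        if (!all(markers %in% colnames(centroids))) {
          stop("unknown marker gene(s) in rule '", level$label[ri], "'")
        }
        if (all(centroids[ci, markers] > level$threshold[ri])) {
          hits <- c(hits, level$label[ri])
        }
      }
      if (length(hits) > 1L) {
        stop(sprintf("cluster %d matches conflicting rules at precedence %s: %s",
                     ci, prec, paste(hits, collapse = ", ")))
      }
      if (length(hits) == 1L) labels[ci] <- hits
    }
  }
  if (!is.null(classification)) {
    classification$labels <- labels
    return(classification)
  }
  labels
}

#' Pseudocolor a boundary-index image by cluster assignment
#'
#' Paints the boundary pixels of each nucleus with the palette color of
#' its cluster, producing the spatial remapping of molecular classes onto
#' the tissue image.
#'
#' @param boundary_index integer boundary-index image
#'   ([export_boundary_index_image()]).
#' @param classification a `plish_classification` (cell `i` is the cell
#'   with `cell_id == i`), or an integer vector of per-cell cluster ids
#'   indexed by cell.
#' @param palette vector of R colors indexed by cluster id.
#' @return an RGB array (rows x cols x 3) in [0, 1]; background black.
#' @export
pseudocolor_map <- function(boundary_index, classification, palette) {
  if (inherits(classification, "plish_classification")) {
    cluster_of <- setNames(classification$cluster, classification$cell_id)
  } else {
    cluster_of <- setNames(classification, seq_along(classification))
  }
  ids <- sort(unique(boundary_index[boundary_index > 0L]))
  missing <- setdiff(as.character(ids), names(cluster_of))
  if (length(missing)) {
    stop("boundary indices missing from the classification: cell(s) ",
         paste(missing, collapse = ", "))
  }
  clusters <- cluster_of[as.character(ids)]
  if (any(clusters > length(palette))) {
    stop("palette has no color for cluster(s) ",
         paste(setdiff(unique(clusters), seq_along(palette)), collapse = ", "))
  }
  rgb <- grDevices::col2rgb(palette) / 255
  out <- array(0, dim = c(nrow(boundary_index), ncol(boundary_index), 3L))
  for (i in seq_along(ids)) {
    sel <- boundary_index == ids[i]
    col <- rgb[, clusters[i]]
    for (chan in 1:3) {
      plane <- out[, , chan]
      plane[sel] <- col[chan]
      out[, , chan] <- plane
    }
  }
  out
}
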