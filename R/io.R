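# Readers and writers for the tabular formats the pipeline touches.
# Conventions: variants use 1-based positions (VCF dialect); segments use
# 1-based inclusive coordinates (SEG dialect); a zero-depth cell is encoded
# as counts 0/0 and its VAF is absent, never 0. All readers reject rather
# than silently coerce malformed input.

#' Construct a read-count matrix
#'
#' @param variants data frame with at least `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` (optionally `gene`, `cluster`); positions must be >= 1 and
#'   `ref != alt`.
#' @param ref,alt non-negative integer matrices (variants x samples) of
#'   reference and mutant read counts, with matching dimnames.
#' @return object of class `"read_counts"`: list with `variants`, `samples`,
#'   `ref`, `alt`.
#' @export
read_counts <- function(variants, ref, alt) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (anyDuplicated(variants$variant_id)) {
    mc_stop("duplicate variant rows", "mc_format_error")
  }
  if (any(variants$pos < 1) || any(variants$ref == variants$alt)) {
    mc_stop("variant positions must be >= 1 and ref must differ from alt", "mc_format_error")
  }
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)) || nrow(ref) != nrow(variants)) {
    mc_stop("ref/alt count matrices must match the variant table", "mc_format_error")
  }
  if (any(ref < 0) || any(alt < 0) || any(ref != floor(ref)) || any(alt != floor(alt))) {
    mc_stop("read counts must be non-negative integers", "mc_format_error")
  }
  mode(ref) <- "integer"
  mode(alt) <- "integer"
  rownames(ref) <- rownames(alt) <- variants$variant_id
  structure(list(variants = variants, samples = colnames(ref), ref = ref, alt = alt),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("<read_counts> %d variants x %d samples\n", nrow(x$ref), length(x$samples)))
  invisible(x)
}

#' Variant allele fractions of a read-count matrix
#'
#' @param counts a [read_counts] object.
#' @return matrix of `alt / (ref + alt)`; `NA` where depth is 0.
#' @export
vaf_matrix <- function(counts) {
  depth <- counts$ref + counts$alt
  ifelse(depth > 0, counts$alt / depth, NA_real_)
}

#' Read a per-variant read-count table (TSV or VCF)
#'
#' The TSV dialect has columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#' `gene`, then one `<sample>_ref` / `<sample>_alt` pair per sample. A
#' `.vcf`/`.vcf.gz` path is parsed instead via its per-sample `AD` fields
#' and yields the identical structure. Sample columns must be declared in
#' `meta` when given.
#'
#' @param path input file.
#' @param meta optional sample metadata table (see [read_sample_meta()]);
#'   samples absent from it are rejected.
#' @return a [read_counts] object.
#' @export
read_variant_counts <- function(path, meta = NULL) {
  if (!file.exists(path)) mc_stop(sprintf("no such file: %s", path), "mc_format_error")
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    counts <- read_variant_counts_vcf(path)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    fixed <- c("variant_id", "chrom", "pos", "ref", "alt", "gene")
    if (!all(fixed[1:5] %in% names(d))) {
      mc_stop("count table must declare variant_id, chrom, pos, ref, alt", "mc_format_error")
    }
    samp_cols <- setdiff(names(d), fixed)
    ref_cols <- grep("_ref$", samp_cols, value = TRUE)
    samples <- sub("_ref$", "", ref_cols)
    if (!length(samples) || !all(paste0(samples, "_alt") %in% samp_cols)) {
      mc_stop("count table must declare <sample>_ref/<sample>_alt column pairs", "mc_format_error")
    }
    ref <- as.matrix(d[, paste0(samples, "_ref"), drop = FALSE])
    alt <- as.matrix(d[, paste0(samples, "_alt"), drop = FALSE])
    if (any(ref < 0) || any(alt < 0)) {
      bad <- which(rowSums(ref < 0 | alt < 0) > 0)[1L]
      mc_stop(sprintf("negative read count in row %d (variant %s)", bad, d$variant_id[bad]),
              "mc_format_error")
    }
    colnames(ref) <- colnames(alt) <- samples
    if (!"gene" %in% names(d)) d$gene <- NA_character_
    counts <- read_counts(d[, fixed[fixed %in% names(d)]], ref, alt)
  }
  if (!is.null(meta) && !all(counts$samples %in% meta$sample_id)) {
    mc_stop(sprintf("samples not declared in metadata: %s",
                    paste(setdiff(counts$samples, meta$sample_id), collapse = ", ")),
            "mc_consistency_error")
  }
  counts
}

read_variant_counts_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || !ncol(ad)) mc_stop("VCF has no per-sample AD fields", "mc_format_error")
  split2 <- function(x, i) suppressWarnings(as.integer(vapply(strsplit(x, ","),
                                                              function(p) p[i] %||% NA_character_, "")))
  ref <- apply(ad, 2L, split2, i = 1L)
  alt <- apply(ad, 2L, split2, i = 2L)
  ref <- matrix(ref, nrow = nrow(ad), dimnames = dimnames(ad))
  alt <- matrix(alt, nrow = nrow(ad), dimnames = dimnames(ad))
  if (anyNA(ref) || anyNA(alt)) mc_stop("malformed AD field in VCF", "mc_format_error")
  ids <- fix[, "ID"]
  ids <- ifelse(is.na(ids) | ids == ".", paste0(fix[, "CHROM"], ":", fix[, "POS"]), ids)
  variants <- data.frame(variant_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                         alt = fix[, "ALT"], gene = NA_character_,
                         stringsAsFactors = FALSE)
  read_counts(variants, ref, alt)
}

#' Write a read-count table in the TSV dialect of [read_variant_counts()]
#'
#' @param counts a [read_counts] object.
#' @param path output file.
#' @export
write_variant_counts <- function(counts, path) {
  d <- counts$variants[, c("variant_id", "chrom", "pos", "ref", "alt")]
  d$gene <- counts$variants$gene %||% NA_character_
  for (s in counts$samples) {
    d[[paste0(s, "_ref")]] <- counts$ref[, s]
    d[[paste0(s, "_alt")]] <- counts$alt[, s]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-style segment observation table
#'
#' Columns `sample`, `chrom`, `start`, `end`, `c`, `folded_baf_dev`,
#' `n_snps`; 1-based inclusive coordinates. Overlapping segments within one
#' sample are rejected.
#'
#' @param path input TSV.
#' @return validated data frame.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) mc_stop(sprintf("no such file: %s", path), "mc_format_error")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "c", "folded_baf_dev", "n_snps")
  if (!all(need %in% names(d))) {
    mc_stop(sprintf("segment table must declare columns: %s", paste(need, collapse = ", ")),
            "mc_format_error")
  }
  if (any(d$start > d$end)) {
    bad <- which(d$start > d$end)[1L]
    mc_stop(sprintf("segment row %d has start > end", bad), "mc_format_error")
  }
  for (key in split(seq_len(nrow(d)), paste(d$sample, d$chrom))) {
    if (length(key) < 2L) next
    seg <- d[key, ][order(d$start[key]), ]
    if (any(seg$start[-1L] <= seg$end[-nrow(seg)])) {
      mc_stop(sprintf("overlapping segments in sample %s on %s", seg$sample[1L], seg$chrom[1L]),
              "mc_consistency_error")
    }
  }
  d[, need]
}

#' Write a segment observation table
#'
#' @param segments data frame as returned by [read_segments()] or
#'   [simulate_baf_segments()].
#' @param path output TSV.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tree_to_newick <- function(tree) {
  build <- function(node) {
    kids <- sort(tree_children(tree, node))
    inner <- if (length(kids)) paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")") else ""
    paste0(inner, node, ":", tree$branch_mutation_count[[node]])
  }
  body <- build(tree$root)
  # a lone root still needs parentheses to be parseable Newick
  if (!length(tree_children(tree, tree$root))) body <- paste0("(", body, ")")
  paste0(body, ";")
}

#' Write a clone tree as JSON and Newick
#'
#' The JSON document carries the full structure (nodes, parents, clusters,
#' CNV events, branch mutation counts and the alternative-parent sets of
#' ambiguous attachments); the Newick string labels nodes and uses branch
#' mutation counts as branch lengths.
#'
#' @param tree a `"clone_tree"`.
#' @param json_path output JSON file.
#' @param newick_path optional output Newick file.
#' @return the Newick string, invisibly.
#' @export
write_tree <- function(tree, json_path, newick_path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  doc <- list(
    nodes = data.frame(node_id = names(tree$parent),
                       parent_id = unname(tree$parent),
                       cluster_id = unname(tree$cluster_id[names(tree$parent)]),
                       branch_mutation_count = unname(tree$branch_mutation_count[names(tree$parent)]),
                       stringsAsFactors = FALSE),
    cnv_events = tree$cnv_events,
    ambiguous = tree$ambiguous
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  nwk <- tree_to_newick(tree)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  invisible(nwk)
}

#' Read a clone tree from its JSON document
#'
#' @param json_path file written by [write_tree()].
#' @return a `"clone_tree"`.
#' @export
read_tree <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  nodes <- doc$nodes
  parent <- stats::setNames(as.character(nodes$parent_id), nodes$node_id)
  parent[is.na(nodes$parent_id) | nodes$parent_id == "NA"] <- NA_character_
  amb <- doc$ambiguous
  if (is.null(amb) || !length(amb)) amb <- list() else amb <- lapply(amb, as.character)
  cnv <- doc$cnv_events
  if (is.null(cnv) || !length(cnv)) cnv <- data.frame(node = character(), stringsAsFactors = FALSE)
  clone_tree(parent,
             cluster_id = stats::setNames(nodes$cluster_id, nodes$node_id),
             branch_mutation_count = stats::setNames(nodes$branch_mutation_count, nodes$node_id),
             cnv_events = as.data.frame(cnv, stringsAsFactors = FALSE),
             ambiguous = amb)
}

#' Write a region-composition table
#'
#' One row per (sample, node) fraction plus the per-sample purity;
#' fractions are re-validated on write (a sample's fractions may not exceed
#' 1 beyond 1e-6).
#'
#' @param comp a `"region_composition"` data frame.
#' @param path output TSV.
#' @export
write_composition <- function(comp, path) {
  sums <- tapply(comp$fraction, comp$sample_id, sum)
  if (any(sums > 1 + 1e-6)) {
    mc_stop(sprintf("fractions of sample %s sum to %.6f > 1", names(sums)[sums > 1 + 1e-6][1L],
                    max(sums)), "mc_invalid_composition")
  }
  if (any(comp$fraction < 0)) mc_stop("negative clone fraction", "mc_invalid_composition")
  utils::write.table(comp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region-composition table
#'
#' @param path file written by [write_composition()].
#' @return a `"region_composition"` data frame.
#' @export
read_composition <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("region_composition", "data.frame")
  d
}

#' Read a sample metadata table
#'
#' Columns `sample_id`, `patient_id`, `tissue_class` (`tumor` or `normal`),
#' `region_label`, optional `spatial_position` (fractional transverse-plane
#' clock position in `[0, 1)`) and `anatomical_site`.
#'
#' @param path input TSV.
#' @return validated data frame.
#' @export
read_sample_meta <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue_class", "region_label")
  if (!all(need %in% names(d))) {
    mc_stop(sprintf("metadata must declare columns: %s", paste(need, collapse = ", ")),
            "mc_format_error")
  }
  if (anyDuplicated(d$sample_id)) mc_stop("duplicate sample_id in metadata", "mc_format_error")
  if (!all(d$tissue_class %in% c("tumor", "normal"))) {
    mc_stop("tissue_class must be 'tumor' or 'normal'", "mc_format_error")
  }
  if ("spatial_position" %in% names(d)) {
    sp <- d$spatial_position
    if (any(!is.na(sp) & (sp < 0 | sp >= 1))) {
      mc_stop("spatial_position must lie in [0, 1)", "mc_format_error")
    }
  }
  d
}

#' Write a sample metadata table
#'
#' @param meta data frame as validated by [read_sample_meta()].
#' @param path output TSV.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
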