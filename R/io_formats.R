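#' Read a GWAS association table
#'
#' Reads a tab- or comma-separated table of SNP identifiers and association
#' p-values. The separator is auto-detected from the header line (tab
#' preferred). Row order is preserved.
#'
#' @param path Path to the table. Must have a header line.
#' @param p_column Name of the p-value column (default `"p"`).
#' @param id_column Name of the SNP identifier column (default `"snp"`).
#' @return A `data.frame` with columns `rsid` (character) and `p` (numeric,
#'   strictly in (0, 1]). Duplicate identifiers are an error.
#' @export
read_gwas_table <- function(path, p_column = "p", id_column = "snp") {
  if (!file.exists(path)) stop("GWAS table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "",
                          colClasses = "character")
  for (col in c(id_column, p_column)) {
    if (!col %in% names(df))
      stop("configuration error: column '", col, "' not found in ", path)
  }
  rsid <- as.character(df[[id_column]])
  p <- suppressWarnings(as.numeric(df[[p_column]]))
  bad <- which(is.na(p) | p <= 0 | p > 1)
  if (length(bad) > 0)
    stop("validation error: p-value outside (0, 1] or non-numeric at row ",
         bad[1L], " (rsid '", rsid[bad[1L]], "')")
  empty <- which(!nzchar(rsid))
  if (length(empty) > 0)
    stop("validation error: empty rsid at row ", empty[1L])
  if (anyDuplicated(rsid) > 0)
    stop("validation error: duplicate rsid '", rsid[duplicated(rsid)][1L], "'")
  message(sprintf("read_gwas_table: %d SNP records from %s", nrow(df), path))
  data.frame(rsid = rsid, p = p, stringsAsFactors = FALSE)
}

#' Write a GWAS association table
#'
#' Inverse of [read_gwas_table()]: writes a tab-separated table with columns
#' `snp` and `p` at full double precision so that write-then-read round-trips
#' exactly.
#'
#' @param snps A `data.frame` with columns `rsid` and `p`.
#' @param path Output path.
#' @export
write_gwas_table <- function(snps, path) {
  df <- data.frame(snp = snps$rsid, p = sprintf("%.17g", snps$p),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction network
#'
#' Supports two-column edge lists and SIF (`source type target [target ...]`;
#' the interaction-type token is ignored; a single-token line declares an
#' isolated node). Self-loops are dropped and duplicate or reciprocal edges
#' collapsed, with counts reported via `message()`.
#'
#' @param path Path to the network file.
#' @param dialect `"auto"` (default; decided from the first line),
#'   `"edge-list"`, or `"sif"`.
#' @return An undirected simple [igraph][igraph::igraph-package] graph whose
#'   vertex names are the gene symbols, in sorted order.
#' @export
read_ppi <- function(path, dialect = c("auto", "edge-list", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("PPI file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  if (length(toks) == 0) {
    warning("read_ppi: empty file ", path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (dialect == "auto")
    dialect <- if (length(toks[[1L]]) == 2L) "edge-list" else "sif"
  from <- character(0); to <- character(0); nodes <- character(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (dialect == "edge-list") {
      if (length(tk) != 2L)
        stop("validation error: malformed edge-list line ", lineno[i],
             " (expected 2 fields, got ", length(tk), ")")
      from <- c(from, tk[1L]); to <- c(to, tk[2L])
    } else {
      if (length(tk) == 1L) {
        nodes <- c(nodes, tk)
      } else if (length(tk) >= 3L) {
        tg <- tk[-(1:2)]
        from <- c(from, rep(tk[1L], length(tg))); to <- c(to, tg)
      } else {
        stop("validation error: malformed SIF line ", lineno[i],
             " (expected 1 or >= 3 fields)")
      }
    }
  }
  nodes <- sort(unique(c(nodes, from, to)))
  n_self <- sum(from == to)
  ok <- from != to
  key <- paste(pmin(from[ok], to[ok]), pmax(from[ok], to[ok]), sep = "\r")
  n_dup <- sum(duplicated(key))
  uk <- !duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pmin(from[ok], to[ok])[uk],
               to = pmax(from[ok], to[ok])[uk],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  message(sprintf(
    "read_ppi: %d nodes, %d edges (%d self-loops dropped, %d duplicate edges collapsed)",
    igraph::vcount(g), igraph::ecount(g), n_self, n_dup))
  g
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated within a term; the universe is the union of all term genes.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a list with `term_id`,
#'   `term_name` (named by term id), `genes` (named list of character
#'   vectors) and `universe` (sorted character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("validation error: GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids) > 0)
    stop("validation error: duplicate term_id '", ids[duplicated(ids)][1L], "'")
  nm <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- ids
  names(nm) <- ids
  structure(list(term_id = ids, term_name = nm, genes = genes,
                 universe = sort(unique(unlist(genes, use.names = FALSE)))),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param collection A `gene_set_collection` as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$term_id, function(id) {
    paste(c(id, collection$term_name[[id]], collection$genes[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, %d genes in universe\n",
              length(x$term_id), length(x$universe)))
  invisible(x)
}

#' Write all pipeline reports to a directory
#'
#' Writes the gene-score table, the module table, the enrichment table, the
#' annotation-network node/edge tables, the run configuration and a
#' plain-text manifest containing an MD5 hash of the configuration, the RNG
#' seed and stage counts. Components missing from `results` are skipped.
#' Numbers are rendered with [fmt_num()]-style deterministic formatting, so
#' a fixed input always yields byte-identical files.
#'
#' @param results A list with any of: `gene_scores`, `modules`,
#'   `enrichment`, `annotation` (list with `nodes` and `edges`), `config`
#'   (a list), `seed`, `counts` (named vector of stage counts).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_report(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$gene_scores)) put(results$gene_scores, "gene_scores.tsv")
  if (!is.null(results$modules)) {
    mods <- results$modules
    put(mods, "modules.tsv")
  }
  if (!is.null(results$enrichment)) put(results$enrichment, "enrichment.tsv")
  if (!is.null(results$annotation)) {
    put(results$annotation$nodes, "annotation_nodes.tsv")
    put(results$annotation$edges, "annotation_edges.tsv")
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(results$config %||% list(), cfg_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, cfg_path)
  manifest <- c(
    sprintf("package=gwasnet %s", as.character(utils::packageVersion("gwasnet"))),
    sprintf("seed=%s", format(results$seed %||% NA)),
    sprintf("config_md5=%s", unname(tools::md5sum(cfg_path))),
    if (!is.null(results$counts))
      sprintf("count_%s=%s", names(results$counts), format(results$counts)),
    sprintf("file=%s", basename(written)))
  man_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, man_path)
  invisible(c(written, man_path))
}
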