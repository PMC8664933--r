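#' Carrier tables: pathogenic-variant carriers by gene and group
#'
#' Records, for each individual, the set of autosomal-recessive disease
#' genes in which they carry a pathogenic/likely-pathogenic (P/LP)
#' variant, together with a social-group label (the endogamous unit).
#'
#' @param individuals data.frame with columns `id` and `group`.
#' @param genes named list mapping each id to a character vector of carried
#'   gene ids (possibly empty).
#' @param gene_universe character vector of all gene ids considered.
#' @return object of class `carrier_table`.
#' @export
carrier_table <- function(individuals, genes, gene_universe) {
  stopifnot(all(c("id", "group") %in% names(individuals)))
  if (any(!nzchar(individuals$group))) stop("group labels must be non-empty")
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids")
  genes <- genes[individuals$id]
  names(genes) <- individuals$id
  genes <- lapply(genes, function(g) if (is.null(g)) character() else g)
  bad <- setdiff(unique(unlist(genes)), gene_universe)
  if (length(bad)) stop("carried genes outside the declared universe: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  structure(list(individuals = individuals, genes = genes,
                 gene_universe = gene_universe),
            class = "carrier_table")
}

#' @export
print.carrier_table <- function(x, ...) {
  cat(sprintf("<carrier_table> %d individuals, %d groups, %d genes, %.2f carried genes/individual\n",
              nrow(x$individuals), length(unique(x$individuals$group)),
              length(x$gene_universe), mean(lengths(x$genes))))
  invisible(x)
}

#' Generate a group-structured synthetic carrier table
#'
#' Per-gene carrier rates come from `carrier_rate_model`. `sharing_boost`
#' b >= 1 introduces within-group correlation via a founder-effect style
#' mechanism: independently per (group, gene), the gene segregates in the
#' group with probability 1/b, and carriers are then drawn at rate b * p
#' (capped at 1). Marginal carrier rates are preserved in expectation
#' while couples from the same group are more likely to carry variants in
#' the same gene — the signature of endogamy-driven recessive risk.
#'
#' @param n_per_group individuals per group (scalar or vector).
#' @param groups character group labels.
#' @param n_genes number of genes in the universe.
#' @param carrier_rate_model per-gene carrier frequency: scalar, vector of
#'   length `n_genes`, or a function `n -> n` rates.
#' @param sharing_boost within-group sharing multiplier (>= 1).
#' @param seed integer seed.
#' @return a [carrier_table()].
#' @export
gen_carrier_table <- function(n_per_group, groups, n_genes = 100,
                              carrier_rate_model = 0.01, sharing_boost = 1,
                              seed = 1) {
  set.seed(seed)
  if (sharing_boost < 1) stop("sharing_boost must be >= 1")
  p <- if (is.function(carrier_rate_model)) carrier_rate_model(n_genes)
       else rep_len(carrier_rate_model, n_genes)
  if (any(p < 0 | p > 1)) stop("carrier rates must be in [0, 1]")
  n_per_group <- rep_len(n_per_group, length(groups))
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  ids <- character(); grp <- character(); genes <- list()
  for (gi in seq_along(groups)) {
    n <- n_per_group[gi]
    seg <- stats::runif(n_genes) < 1 / sharing_boost
    rate <- ifelse(seg, pmin(1, p * sharing_boost), 0)
    carry <- matrix(stats::runif(n * n_genes) < rep(rate, each = n), nrow = n)
    id_g <- sprintf("%s_%03d", groups[gi], seq_len(n))
    ids <- c(ids, id_g); grp <- c(grp, rep(groups[gi], n))
    genes <- c(genes, lapply(seq_len(n), function(i) gene_ids[carry[i, ]]))
  }
  names(genes) <- ids
  carrier_table(data.frame(id = ids, group = grp, stringsAsFactors = FALSE),
                genes, gene_ids)
}

#' Read/write carrier tables
#'
#' Tab-delimited with header: individual, group, semicolon-joined gene
#' list (empty field for non-carriers). A `#universe:` comment line
#' preserves the gene universe.
#'
#' @param path file path.
#' @return [read_carrier_table()]: a [carrier_table()].
#' @export
read_carrier_table <- function(path) {
  ln <- readLines(path)
  uni <- character()
  if (startsWith(ln[1], "#universe:")) {
    uni <- strsplit(sub("^#universe:", "", ln[1]), ";")[[1]]
    ln <- ln[-1]
  }
  d <- utils::read.table(text = ln, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = NULL,
                         colClasses = "character")
  genes <- lapply(d$genes, function(s)
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";")[[1]])
  names(genes) <- d$individual
  if (!length(uni)) uni <- sort(unique(unlist(genes)))
  carrier_table(data.frame(id = d$individual, group = d$group,
                           stringsAsFactors = FALSE), genes, uni)
}

#' @rdname read_carrier_table
#' @param ct a [carrier_table()].
#' @export
write_carrier_table <- function(ct, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#universe:", paste(ct$gene_universe, collapse = ";")), con)
  writeLines("individual\tgroup\tgenes", con)
  writeLines(sprintf("%s\t%s\t%s", ct$individuals$id, ct$individuals$group,
                     vapply(ct$genes, paste, "", collapse = ";")), con)
  invisible(path)
}
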