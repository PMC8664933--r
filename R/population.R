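#' Simulate an endogamous population with per-generation consanguinity
#'
#' Forward-in-time simulation of a closed population of `n_pairs`
#' reproducing couples. Each generation, every new couple is a degree-i
#' relative pair (connected by a single path) with probability `r[i]`, and
#' is otherwise formed by mating children of two distinct random couples
#' (non-sibs; deeper background relatedness accumulates freely, which is
#' the endogamy being modelled).
#'
#' Consanguineous couples are realised without perturbing the gene pool:
#' a degree-1 (sibling) couple is two children of one existing couple; a
#' degree-i couple (i >= 2) is a pair of children of two existing couples
#' that are connected by a degree-(i-1) relative pair, located by
#' searching the recorded pedigree (members sharing an ancestral couple at
#' depth i-1 and none shallower). All children are born to couples of the
#' previous generation, so the offspring-number distribution stays
#' Wright-Fisher-like and the effective population size is not distorted
#' by the consanguinity machinery. In the first generations, while the
#' pedigree is shallower than the requested degree, such couples fall back
#' to random mating (consanguinity "switches on" once the pedigree is deep
#' enough); with many simulated generations this burn-in is negligible.
#' A degree that is feasible in depth but cannot be realised (no relative
#' pair available at the requested degree) is an error, not a silent
#' fallback.
#'
#' The returned individuals are the children of the final generation's
#' couples (two per couple), so their autozygosity reflects parental
#' relatedness drawn from `r`, and cross-couple IBD reflects the
#' population's drift and endogamy.
#'
#' @param founders a [genotype_panel()] supplying founder haplotypes, or an
#'   integer number of abstract founders (tract-only mode). Must be at
#'   least `2 * n_pairs`.
#' @param n_pairs reproducing couples per generation.
#' @param generations number of couple generations to simulate (>= 1).
#' @param r numeric consanguinity rates (r1..r5, padded with zeros);
#'   `sum(r)` must be <= 1 for a forward simulation.
#' @param map a [genetic_map()].
#' @param seed integer seed.
#' @param output `"balanced"` (default): two children from every final
#'   couple; `"random"`: 2 * n_pairs children whose parent couples are
#'   drawn uniformly with replacement, i.e. Wright-Fisher sampling, which
#'   reproduces the model's sib-pair (TMRCA = 1) mass in cross-individual
#'   comparisons.
#' @return object of class `sim_population`: list with `individuals`
#'   (list of 2 * n_pairs mosaic individuals), `sample_ids`, `couple_of`
#'   (couple index of each final individual), `map`, `founder_panel`
#'   (NULL in tract-only mode), `pedigree` (data.frame id, father, mother,
#'   generation), and the simulation parameters.
#' @export
gen_endogamous_population <- function(founders, n_pairs, generations, r,
                                      map = uniform_genome_map(), seed = 1,
                                      output = c("balanced", "random")) {
  output <- match.arg(output)
  if (length(r) > 5) stop("at most five rate components")
  r <- c(r, numeric(5 - length(r)))
  if (any(r < 0)) stop("rates must be non-negative")
  if (sum(r) > 1) stop("infeasible r: component sum ", signif(sum(r), 4),
                       " > 1 cannot be realised forward in time")
  kinship_from_r(r)  # guard k < 1/4
  if (generations < 1) stop("need generations >= 1")
  if (n_pairs < 3) stop("need n_pairs >= 3")
  panel <- NULL
  if (inherits(founders, "genotype_panel")) {
    panel <- founders
    n_founders <- length(panel$samples)
  } else n_founders <- as.integer(founders)
  if (n_founders < 2 * n_pairs)
    stop("need at least 2 * n_pairs founders, have ", n_founders)
  set.seed(seed)
  chrom_len <- map_lengths(map)$cM

  ped <- new.env(parent = emptyenv())
  cap <- 1024L
  ped$father <- integer(cap); ped$mother <- integer(cap)
  ped$generation <- integer(cap); ped$n <- 0L
  new_id <- function(fa, mo, gen) {
    i <- ped$n + 1L
    if (i > length(ped$father)) {        # grow by doubling
      grow <- function(x) c(x, integer(length(x)))
      ped$father <- grow(ped$father); ped$mother <- grow(ped$mother)
      ped$generation <- grow(ped$generation)
    }
    ped$n <- i
    ped$father[i] <- fa; ped$mother[i] <- mo; ped$generation[i] <- gen
    i
  }

  pick <- sample.int(n_founders, 2L * n_pairs)
  ncouple <- 0L
  new_cid <- function() { ncouple <<- ncouple + 1L; ncouple }
  # a member carries its mosaics, pedigree id, and ancestor-couple ids at
  # depths 1..4 (1, 2, 4, 8 ids) for the relative-pair search
  make_founder <- function(w, gen) {
    list(id = new_id(0L, 0L, gen),
         ind = .founder_ind(chrom_len, 2L * pick[w] - 1L, 2L * pick[w]),
         anc = list(integer(0), integer(0), integer(0), integer(0)))
  }
  born <- function(couple, gen) {
    fa <- couple$a; mo <- couple$b
    list(id = new_id(fa$id, mo$id, gen),
         ind = .child_of(fa$ind, mo$ind, chrom_len),
         anc = list(couple$cid,
                    c(fa$anc[[1]], mo$anc[[1]]),
                    c(fa$anc[[2]], mo$anc[[2]]),
                    c(fa$anc[[3]], mo$anc[[3]])))
  }

  # couples[[g + 1]] holds generation g: list(a, b, cid)
  prev <- lapply(seq_len(n_pairs), function(ci)
    list(a = make_founder(2L * ci - 1L, 0L), b = make_founder(2L * ci, 0L),
         cid = new_cid()))

  cum_r <- cumsum(r)
  for (g in seq_len(generations)) {
    members <- vector("list", 2L * n_pairs)        # flattened prev members
    mem_couple <- integer(2L * n_pairs)
    for (ci in seq_len(n_pairs)) {
      members[[2L * ci - 1L]] <- prev[[ci]]$a
      members[[2L * ci]] <- prev[[ci]]$b
      mem_couple[c(2L * ci - 1L, 2L * ci)] <- ci
    }
    # lazy per-depth index: ancestor couple id -> member indices
    anc_index <- list()
    get_index <- function(j) {
      key <- as.character(j)
      if (is.null(anc_index[[key]])) {
        ids <- lapply(members, function(m) m$anc[[j]])
        anc_index[[key]] <<- split(rep(seq_along(members), lengths(ids)),
                                   unlist(ids))
      }
      anc_index[[key]]
    }
    # find two distinct couples connected by a degree-j member pair
    find_connected <- function(j) {
      idx <- get_index(j)
      grp <- idx[lengths(idx) >= 2L]
      if (!length(grp)) return(NULL)
      for (try in seq_len(80L)) {
        cand <- grp[[sample.int(length(grp), 1L)]]
        xy <- cand[sample.int(length(cand), 2L)]
        if (mem_couple[xy[1]] == mem_couple[xy[2]]) next
        shallower <- FALSE
        if (j > 1L) for (k in seq_len(j - 1L)) {
          if (length(intersect(members[[xy[1]]]$anc[[k]],
                               members[[xy[2]]]$anc[[k]]))) {
            shallower <- TRUE; break
          }
        }
        if (!shallower) return(mem_couple[xy])
      }
      NULL
    }
    gen_new <- vector("list", n_pairs)
    u <- stats::runif(n_pairs)
    for (ci in seq_len(n_pairs)) {
      deg <- findInterval(u[ci], cum_r, left.open = TRUE) + 1L
      if (u[ci] >= cum_r[5]) deg <- 0L
      if (deg > 0L && g < deg) deg <- 0L   # pedigree too shallow: burn-in
      if (deg == 1L) {
        pc <- sample.int(n_pairs, 1L)
        gen_new[[ci]] <- list(a = born(prev[[pc]], g), b = born(prev[[pc]], g),
                              cid = new_cid())
      } else if (deg >= 2L) {
        cc <- find_connected(deg - 1L)
        if (is.null(cc))
          stop("infeasible r given n_pairs: no degree-", deg,
               " relative pair available at generation ", g)
        gen_new[[ci]] <- list(a = born(prev[[cc[1]]], g),
                              b = born(prev[[cc[2]]], g), cid = new_cid())
      } else {
        pc <- sample.int(n_pairs, 2L)
        gen_new[[ci]] <- list(a = born(prev[[pc[1]]], g),
                              b = born(prev[[pc[2]]], g), cid = new_cid())
      }
    }
    prev <- gen_new
  }

  # output children of the final couples
  out_ind <- vector("list", 2L * n_pairs)
  couple_of <- if (output == "balanced") rep(seq_len(n_pairs), each = 2L)
               else sort(sample.int(n_pairs, 2L * n_pairs, replace = TRUE))
  for (w in seq_len(2L * n_pairs)) {
    ch <- born(prev[[couple_of[w]]], generations + 1L)
    out_ind[[w]] <- ch$ind
  }
  structure(list(
    individuals = out_ind,
    sample_ids = sprintf("I%04d", seq_len(2L * n_pairs)),
    couple_of = couple_of,
    map = map, founder_panel = panel,
    pedigree = data.frame(id = seq_len(ped$n),
                          father = ped$father[seq_len(ped$n)],
                          mother = ped$mother[seq_len(ped$n)],
                          generation = ped$generation[seq_len(ped$n)]),
    r = r, n_pairs = n_pairs, generations = generations, seed = seed
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d individuals after %d generations, n_pairs %d, sum(r) = %.3g\n",
              length(x$individuals), x$generations, x$n_pairs, sum(x$r)))
  invisible(x)
}

#' Truth autozygosity (ROH) segments of a simulated population
#'
#' Maximal intervals where an individual's two haplotypes descend from the
#' same founder haplotype.
#'
#' @param pop a `sim_population`.
#' @param ids subset of individual indices (default all).
#' @return an ROH [segment_table()].
#' @export
truth_roh_segments <- function(pop, ids = seq_along(pop$individuals)) {
  len <- map_lengths(pop$map)
  tabs <- lapply(ids, function(i)
    .truth_tracts_one(pop$individuals[[i]], pop$map, len, pop$sample_ids[i]))
  do.call(rbind_segments, tabs)
}

#' Truth IBD segments between individuals of a simulated population
#'
#' Maximal intervals where two haplotypes in *different* individuals
#' descend from the same founder haplotype; one row per haplotype pair per
#' interval, which matches the chromosome-pair denominator used by the
#' empirical IBD footprint.
#'
#' @param pop a `sim_population`.
#' @param ids individual indices to compare (default one child per couple,
#'   avoiding sib pairs).
#' @param min_cM drop shared intervals shorter than this (default 1 cM,
#'   keeps the table small).
#' @param segment_def `"path"` (default): segments delimited by every
#'   recombination on the connecting lineage paths, the definition the
#'   expected-footprint theory counts; `"identity"`: maximal runs of
#'   founder-haplotype identity, what an idealised identity-based caller
#'   reports (longer, since recombinations that reshuffle ancestry without
#'   changing the founder source do not interrupt identity).
#' @return an IBD [segment_table()].
#' @export
truth_ibd_segments <- function(pop, ids = which(!duplicated(pop$couple_of)),
                               min_cM = 1, segment_def = "path") {
  map <- pop$map
  len <- map_lengths(map)
  f <- .seg_fun(segment_def)
  rows <- list(); nr <- 0L
  for (ii in seq_along(ids)) for (jj in seq_len(ii - 1L)) {
    i <- ids[ii]; j <- ids[jj]
    A <- pop$individuals[[i]]; B <- pop$individuals[[j]]
    for (ci in seq_along(len$chrom)) {
      for (ha in list(A$h1[[ci]], A$h2[[ci]])) for (hb in list(B$h1[[ci]], B$h2[[ci]])) {
        iv <- f(ha, hb)
        if (is.null(iv)) next
        keep <- (iv[, 2] - iv[, 1]) >= min_cM
        if (!any(keep)) next
        iv <- iv[keep, , drop = FALSE]
        nr <- nr + 1L
        rows[[nr]] <- data.frame(a = pop$sample_ids[i], b = pop$sample_ids[j],
                                 chrom = len$chrom[ci],
                                 start = iv[, 1], end = iv[, 2])
      }
    }
  }
  if (!nr) return(segment_table())
  d <- do.call(rbind, rows)
  cm0 <- vapply(d$chrom, function(ch) min(.map_chrom(map, ch)$cM), numeric(1))
  start_cM <- d$start + cm0; end_cM <- d$end + cm0
  segment_table(carrier_a = d$a, carrier_b = d$b, chrom = d$chrom,
                start_bp = vapply(seq_len(nrow(d)), function(i)
                  cM_to_bp(map, d$chrom[i], start_cM[i]), numeric(1)),
                end_bp = vapply(seq_len(nrow(d)), function(i)
                  cM_to_bp(map, d$chrom[i], end_cM[i]), numeric(1)) + 1,
                start_cM = start_cM, end_cM = end_cM)
}

# fast lengths-only extraction (footprints need only cM lengths).
# segment_def "path": path-recombination-delimited segments, the definition
# behind the expected-footprint theory; "identity": maximal founder-identity
# runs, what an idealised identity-based caller would report.
.seg_fun <- function(segment_def = c("path", "identity")) {
  segment_def <- match.arg(segment_def)
  if (segment_def == "path") .mosaic_ibd else .mosaic_shared
}

.pop_roh_lengths <- function(pop, ids = seq_along(pop$individuals),
                             segment_def = "path") {
  f <- .seg_fun(segment_def)
  unlist(lapply(ids, function(i) {
    ind <- pop$individuals[[i]]
    unlist(lapply(seq_along(ind$h1), function(ci) {
      x <- f(ind$h1[[ci]], ind$h2[[ci]])
      if (is.null(x)) numeric(0) else x[, 2] - x[, 1]
    }), use.names = FALSE)
  }), use.names = FALSE)
}

.pop_ibd_lengths <- function(pop, ids = which(!duplicated(pop$couple_of)),
                             min_cM = 1, segment_def = "path") {
  f <- .seg_fun(segment_def)
  out <- vector("list", 4096L); nr <- 0L
  for (ii in seq_along(ids)) for (jj in seq_len(ii - 1L)) {
    A <- pop$individuals[[ids[ii]]]; B <- pop$individuals[[ids[jj]]]
    for (ci in seq_along(A$h1)) {
      for (ha in list(A$h1[[ci]], A$h2[[ci]]))
        for (hb in list(B$h1[[ci]], B$h2[[ci]])) {
          x <- f(ha, hb)
          if (is.null(x)) next
          l <- x[, 2] - x[, 1]
          l <- l[l >= min_cM]
          if (length(l)) { nr <- nr + 1L; out[[nr]] <- l }
        }
    }
  }
  unlist(out[seq_len(nr)], use.names = FALSE)
}

# wrap bare lengths as a minimal ROH/IBD segment table on a fake axis so the
# public empirical_footprint() can consume them (positions are irrelevant to
# footprints, only lengths matter)
.lengths_as_segments <- function(l, ibd = FALSE) {
  if (!length(l)) return(segment_table())
  segment_table(carrier_a = sprintf("a%d", seq_along(l)),
                carrier_b = if (ibd) sprintf("b%d", seq_along(l)) else NA_character_,
                chrom = "1", start_bp = 1, end_bp = 2,
                start_cM = 0, end_cM = l)
}

#' Combine segment tables
#' @param ... `segment_table`s.
#' @return a single `segment_table`.
#' @export
rbind_segments <- function(...) {
  tabs <- Filter(function(x) nrow(x) > 0, list(...))
  if (!length(tabs)) return(segment_table())
  d <- do.call(rbind, lapply(tabs, as.data.frame))
  class(d) <- c("segment_table", "data.frame")
  rownames(d) <- NULL
  d
}

#' Materialise a simulated population as a genotype panel
#'
#' Looks up each individual's mosaic against the founder panel's
#' haplotypes at the panel's sites. Only available when the population was
#' simulated from a [genotype_panel()].
#'
#' @param pop a `sim_population`.
#' @return a phased [genotype_panel()].
#' @export
as_genotype_panel <- function(pop) {
  panel <- pop$founder_panel
  if (is.null(panel)) stop("population was simulated in tract-only mode")
  sp <- .panel_site_split(panel, pop$map)
  n <- length(pop$individuals)
  haps <- matrix(0L, nrow = 2L * n, ncol = nrow(panel$sites))
  for (i in seq_len(n)) {
    ind <- pop$individuals[[i]]
    haps[2L * i - 1L, ] <- .mosaic_alleles(ind$h1, sp$cm, sp$idx, panel$haps)
    haps[2L * i, ] <- .mosaic_alleles(ind$h2, sp$cm, sp$idx, panel$haps)
  }
  genotype_panel(pop$sample_ids, panel$sites, haps)
}
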