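#' The ten consanguineous-union classes
#'
#' Names of the ten modelled classes of parental union: sibling, avuncular
#' unions repeated over one to three consecutive generations, first-cousin
#' unions repeated over one to three consecutive generations, first cousin
#' once removed (FCOR), second cousin, and unrelated. "Repeated over g
#' generations" means the same union type occurs in g consecutive ancestral
#' generations (e.g. for `first_cousin_g2` the focal parents are first
#' cousins *and* each pair of focal grandparents were first cousins), which
#' is the reading under which an offspring of a gen-2 first-cousin union is
#' also the offspring of second cousins by two routes, and of a gen-3 union
#' also of third cousins by three routes.
#'
#' @format character vector of length 10.
#' @export
union_classes <- c("sibling",
                   "avuncular_g1", "avuncular_g2", "avuncular_g3",
                   "first_cousin_g1", "first_cousin_g2", "first_cousin_g3",
                   "first_cousin_once_removed", "second_cousin", "unrelated")

# --- tiny pedigree-builder DSL (internal) ----------------------------------

.ped_new <- function() {
  env <- new.env(parent = emptyenv())
  env$id <- integer(); env$father <- integer(); env$mother <- integer()
  env
}
.ped_add <- function(p, father = NA_integer_, mother = NA_integer_) {
  i <- length(p$id) + 1L
  p$id[i] <- i; p$father[i] <- father; p$mother[i] <- mother
  i
}
.ped_df <- function(p, focal) {
  d <- data.frame(id = p$id, father = p$father, mother = p$mother)
  gen <- integer(nrow(d))
  for (i in seq_len(nrow(d)))
    gen[i] <- if (is.na(d$father[i])) 0L else max(gen[d$father[i]], gen[d$mother[i]]) + 1L
  d$generation <- gen
  list(members = d, focal = focal)
}

#' Build the minimal pedigree realising a union class
#'
#' @param union_class one of [union_classes].
#' @return a `pedigree`: list with `members` (data.frame id, father, mother,
#'   generation; founders have NA parents), `focal` (id of the focal
#'   offspring), `class`, and `expected_f` (the focal's exact expected
#'   inbreeding coefficient, computed from the pedigree by the kinship
#'   recursion).
#' @export
build_union_pedigree <- function(union_class) {
  if (!union_class %in% union_classes)
    stop("unknown union class: ", union_class)
  p <- .ped_new()
  f <- function() .ped_add(p)                 # founder
  c2 <- function(fa, mo) .ped_add(p, fa, mo)  # child
  focal <- switch(union_class,
    sibling = {
      A <- f(); B <- f(); X <- c2(A, B); Y <- c2(A, B); c2(X, Y)
    },
    avuncular_g1 = {
      A <- f(); B <- f(); U <- c2(A, B); W <- c2(A, B)
      N <- c2(W, f()); c2(U, N)
    },
    avuncular_g2 = {
      G1 <- f(); G2 <- f()
      c1 <- c2(G1, G2); Wp <- c2(G1, G2); cc2 <- c2(Wp, f())
      Sw <- c2(G1, G2)
      U <- c2(c1, cc2); W <- c2(c1, cc2); N <- c2(W, Sw); c2(U, N)
    },
    avuncular_g3 = {
      H1 <- f(); H2 <- f()
      g1 <- c2(H1, H2); Vp <- c2(H1, H2); g2 <- c2(Vp, f())
      fW <- c2(H1, H2)
      c1 <- c2(g1, g2); Wp <- c2(g1, g2); cc2 <- c2(Wp, fW)
      Sw <- c2(g1, g2)
      U <- c2(c1, cc2); W <- c2(c1, cc2); N <- c2(W, Sw); c2(U, N)
    },
    first_cousin_g1 = {
      A <- f(); B <- f(); X <- c2(A, B); Y <- c2(A, B)
      P1 <- c2(X, f()); P2 <- c2(Y, f()); c2(P1, P2)
    },
    first_cousin_g2 = {
      pa1 <- f(); pa2 <- f(); pb1 <- f(); pb2 <- f()
      A <- c2(pa1, pa2); SibA <- c2(pa1, pa2)
      B <- c2(pb1, pb2); SibB <- c2(pb1, pb2)
      X <- c2(A, B); Y <- c2(A, B)
      Sx <- c2(SibA, f()); Sy <- c2(SibB, f())
      P1 <- c2(X, Sx); P2 <- c2(Y, Sy); c2(P1, P2)
    },
    first_cousin_g3 = {
      e1 <- f(); e2 <- f()
      d11 <- c2(e1, e2); d21 <- c2(e1, e2)
      f11 <- f(); f12 <- f(); d12 <- c2(f11, f12); s12 <- c2(f11, f12)
      f21 <- f(); f22 <- f(); d22 <- c2(f21, f22); s22 <- c2(f21, f22)
      A <- c2(d11, d12); SibA <- c2(d11, d12)
      B <- c2(d21, d22); SibB <- c2(d21, d22)
      fA <- c2(s12, f()); fB <- c2(s22, f())
      X <- c2(A, B); Y <- c2(A, B)
      Sx <- c2(SibA, fA); Sy <- c2(SibB, fB)
      P1 <- c2(X, Sx); P2 <- c2(Y, Sy); c2(P1, P2)
    },
    first_cousin_once_removed = {
      A <- f(); B <- f(); X <- c2(A, B); Y <- c2(A, B)
      P1 <- c2(X, f()); Bc <- c2(Y, f()); D <- c2(Bc, f()); c2(P1, D)
    },
    second_cousin = {
      A <- f(); B <- f(); X <- c2(A, B); Y <- c2(A, B)
      C1 <- c2(X, f()); C2 <- c2(Y, f())
      P1 <- c2(C1, f()); P2 <- c2(C2, f()); c2(P1, P2)
    },
    unrelated = {
      c2(f(), f())
    })
  ped <- .ped_df(p, focal)
  ped$class <- union_class
  fo <- ped$members[focal, ]
  ped$expected_f <- pedigree_kinship(ped, fo$father, fo$mother)
  class(ped) <- "pedigree"
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> class %s: %d members, focal id %d, expected F = %.6g\n",
              x$class, nrow(x$members), x$focal, x$expected_f))
  invisible(x)
}

#' Kinship coefficient between two pedigree members
#'
#' Standard recursive kinship: phi(i,i) = (1 + F_i)/2 and
#' phi(i,j) = (phi(father_i, j) + phi(mother_i, j))/2 recursing on the
#' later-generation member; founders are mutually unrelated and non-inbred.
#' The focal offspring's expected inbreeding coefficient equals the kinship
#' of its parents.
#'
#' @param ped a `pedigree` (or any list with a `members` data.frame).
#' @param i,j member ids.
#' @return the kinship coefficient.
#' @export
pedigree_kinship <- function(ped, i, j) {
  m <- ped$members
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (a == b) {
      if (is.na(m$father[a])) 0.5 else 0.5 * (1 + phi(m$father[a], m$mother[a]))
    } else {
      # recurse on the later-generation member
      if (m$generation[a] > m$generation[b]) { tmp <- a; a <- b; b <- tmp }
      if (is.na(m$father[b])) 0 else 0.5 * (phi(a, m$father[b]) + phi(a, m$mother[b]))
    }
    memo[[key]] <- v
    v
  }
  phi(as.integer(i), as.integer(j))
}

#' Simulate a focal offspring down a pedigree
#'
#' Fills the pedigree founders with haplotypes (fresh unrelated founder
#' haplotypes by default, or individuals drawn without replacement from a
#' supplied pool), then performs meiosis generation by generation down to
#' the focal offspring.
#'
#' Truth autozygosity tracts are the maximal intervals where the focal
#' offspring's two haplotypes descend from the same founder haplotype;
#' they are returned as an ROH-type [segment_table()] in bp and cM.
#'
#' @param pedigree a pedigree from [build_union_pedigree()].
#' @param map a [genetic_map()].
#' @param founder_pool optional [genotype_panel()]; pedigree founders are
#'   drawn from it without replacement and the focal genotype is
#'   materialised at the panel's sites. With `NULL` (truth-tract mode) only
#'   tract structure is simulated and `genotype` is `NULL`.
#' @param seed optional integer seed.
#' @param sample_id carrier id used in the returned tract table.
#' @return list with `truth_tracts` (a `segment_table`), `genotype`
#'   (2 x M matrix of phased alleles, or NULL), and `froh_true`
#'   (cM fraction of the genome in truth tracts).
#' @export
simulate_offspring <- function(pedigree, map, founder_pool = NULL, seed = NULL,
                               sample_id = "offspring") {
  if (!is.null(seed)) set.seed(seed)
  len <- map_lengths(map)
  chrom_len <- len$cM
  m <- pedigree$members
  founders <- which(is.na(m$father))
  inds <- vector("list", nrow(m))
  if (is.null(founder_pool)) {
    for (w in seq_along(founders))
      inds[[founders[w]]] <- .founder_ind(chrom_len, 2L * w - 1L, 2L * w)
  } else {
    stopifnot(inherits(founder_pool, "genotype_panel"))
    npool <- length(founder_pool$samples)
    if (npool < length(founders)) stop("founder pool exhausted: need ",
                                       length(founders), ", have ", npool)
    pick <- sample.int(npool, length(founders))
    for (w in seq_along(founders))
      inds[[founders[w]]] <- .founder_ind(chrom_len, 2L * pick[w] - 1L, 2L * pick[w])
  }
  for (i in order(m$generation)) {
    if (is.na(m$father[i])) next
    inds[[i]] <- .child_of(inds[[m$father[i]]], inds[[m$mother[i]]], chrom_len)
  }
  focal <- inds[[pedigree$focal]]
  tt <- .truth_tracts_one(focal, map, len, sample_id)
  genotype <- NULL
  if (!is.null(founder_pool)) {
    sp <- .panel_site_split(founder_pool, map)
    genotype <- rbind(
      .mosaic_alleles(focal$h1, sp$cm, sp$idx, founder_pool$haps),
      .mosaic_alleles(focal$h2, sp$cm, sp$idx, founder_pool$haps))
  }
  list(truth_tracts = tt, genotype = genotype,
       froh_true = sum(tt$length_cM) / sum(chrom_len))
}

# autozygosity tracts of one individual as a segment_table
.truth_tracts_one <- function(ind, map, len = map_lengths(map), sample_id = "x") {
  rows <- vector("list", length(len$chrom))
  for (ci in seq_along(len$chrom)) {
    iv <- .mosaic_shared(ind$h1[[ci]], ind$h2[[ci]])
    if (is.null(iv)) next
    ch <- len$chrom[ci]
    cm0 <- min(.map_chrom(map, ch)$cM)
    rows[[ci]] <- data.frame(chrom = ch,
                             start = iv[, 1] + cm0, end = iv[, 2] + cm0,
                             start_bp = cM_to_bp(map, ch, iv[, 1] + cm0),
                             end_bp = cM_to_bp(map, ch, iv[, 2] + cm0) + 1)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(segment_table())
  segment_table(
    carrier_a = rep(sample_id, nrow(rows)), carrier_b = NA_character_,
    chrom = rows$chrom,
    start_bp = rows$start_bp, end_bp = rows$end_bp,
    start_cM = rows$start, end_cM = rows$end)
}

# fast path: simulate one focal offspring, return tract cM lengths only
.offspring_tract_lengths <- function(peds_env, ped, chrom_len) {
  m <- ped$members
  founders <- which(is.na(m$father))
  inds <- vector("list", nrow(m))
  for (w in seq_along(founders))
    inds[[founders[w]]] <- .founder_ind(chrom_len, 2L * w - 1L, 2L * w)
  for (i in order(m$generation)) {
    if (is.na(m$father[i])) next
    inds[[i]] <- .child_of(inds[[m$father[i]]], inds[[m$mother[i]]], chrom_len)
  }
  focal <- inds[[ped$focal]]
  unlist(lapply(seq_along(chrom_len), function(ci)
    .mosaic_shared_lengths(focal$h1[[ci]], focal$h2[[ci]])), use.names = FALSE)
}

#' Simulate replicate offspring for each union class
#'
#' Convenience wrapper used by the classifier experiment: simulates `n`
#' focal offspring per requested class in truth-tract mode and returns
#' their per-individual tract tables.
#'
#' @param classes character vector of union classes.
#' @param n replicates per class.
#' @param map a [genetic_map()].
#' @param seed master seed (class- and replicate-specific child seeds are
#'   derived from it).
#' @return data.frame with columns `class`, `rep`, `froh_true` and a list
#'   column `tract_cM` holding each offspring's truth-tract lengths in cM.
#' @export
simulate_union_cohort <- function(classes = union_classes, n = 500,
                                  map = uniform_genome_map(), seed = 1) {
  peds <- lapply(classes, build_union_pedigree)
  names(peds) <- classes
  chrom_len <- map_lengths(map)$cM
  genome_cM <- sum(chrom_len)
  out <- vector("list", length(classes) * n)
  k <- 0L
  for (cl in classes) {
    .with_child_seed(seed, paste0("cohort/", cl))
    for (r in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- .offspring_tract_lengths(NULL, peds[[cl]], chrom_len)
    }
  }
  data.frame(
    class = rep(classes, each = n),
    rep = rep(seq_len(n), length(classes)),
    froh_true = vapply(out, sum, 1) / genome_cM,
    tract_cM = I(out)
  )
}

#' Write a pedigree sidecar file
#'
#' Tab-delimited columns: child, father, mother, generation (founders have
#' father/mother 0).
#'
#' @param ped a `pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  m <- ped$members
  out <- data.frame(child = m$id,
                    father = ifelse(is.na(m$father), 0L, m$father),
                    mother = ifelse(is.na(m$mother), 0L, m$mother),
                    generation = m$generation)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
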