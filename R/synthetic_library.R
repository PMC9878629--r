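# Seeded generator of chemically valid synthetic libraries with controlled
# scaffold-diversity structure. Stands in for real compound collections in
# tests and examples: the scaffold census of the emitted library is known
# by construction.

# Acyclic substituent chains (first element bonds to the scaffold; all
# bonds single, so decoration never changes the Bemis-Murcko scaffold).
.SUBSTITUENTS <- list(
  "C", "O", "N", "F", "Cl",
  c("C", "C"), c("C", "O"), c("C", "N"), c("O", "C"),
  c("C", "C", "C"), c("C", "C", "O"), c("C", "O", "C"), c("C", "C", "N"))

# Run code under a temporary RNG state so generation is reproducible from
# the spec seed without disturbing the caller's RNG.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Specification of a synthetic chemical library
#'
#' Defines the target composition of a generated library: its size, how
#' many distinct cyclic scaffolds it uses, which fraction of those are
#' singletons (used by exactly one molecule), how skewed the frequencies
#' of the remaining scaffolds are, and what fraction of molecules is
#' acyclic.
#'
#' @param M total number of molecules.
#' @param n_scaffolds number of distinct cyclic scaffolds.
#' @param singleton_fraction fraction of scaffolds used exactly once
#'   (default 0.5, in the range observed for real natural-product
#'   libraries).
#' @param skew Zipf exponent `>= 0` for the frequencies of the
#'   non-singleton scaffolds; 0 = as even as integer counts allow, larger
#'   values concentrate molecules on few scaffolds (default 1).
#' @param acyclic_fraction fraction of molecules without rings
#'   (default 0.05).
#' @param seed RNG seed; the whole library is reproducible from it.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(M, n_scaffolds, singleton_fraction = 0.5,
                           skew = 1, acyclic_fraction = 0.05, seed = 1L) {
  stopifnot(M >= 1, n_scaffolds >= 0, skew >= 0,
            singleton_fraction >= 0, singleton_fraction <= 1,
            acyclic_fraction >= 0, acyclic_fraction <= 1)
  n_acyclic <- round(acyclic_fraction * M)
  if (M - n_acyclic == 0L) n_scaffolds <- 0L  # all-acyclic library
  if (n_scaffolds > M - n_acyclic)
    stop("infeasible spec: n_scaffolds exceeds the number of cyclic molecules")
  if (n_scaffolds == 0L && M > n_acyclic)
    stop("infeasible spec: cyclic molecules need at least one scaffold")
  structure(
    list(M = as.integer(M), n_scaffolds = as.integer(n_scaffolds),
         singleton_fraction = singleton_fraction, skew = skew,
         acyclic_fraction = acyclic_fraction, seed = as.integer(seed)),
    class = "SyntheticSpec")
}

#' Built-in scaffold vocabulary
#'
#' Canonical GNB scaffold keys (ring systems, fused systems, and linked
#' ring pairs) bundled with the package; every entry is its own
#' Bemis-Murcko GNB scaffold.
#'
#' @return character vector of canonical SMILES.
#' @export
scaffold_vocabulary <- function() {
  path <- system.file("extdata", "scaffold_vocabulary.smi",
                      package = "scafdiv", mustWork = TRUE)
  readLines(path)
}

# Split r molecules over k scaffolds following Zipf(skew) weights, each
# scaffold receiving at least `minimum`; deterministic largest-remainder
# allocation.
#' @noRd
zipf_allocation <- function(r, k, skew, minimum = 2L) {
  if (k == 0L) return(integer(0))
  if (r < minimum * k) stop("infeasible allocation")
  w <- seq_len(k)^(-skew)
  extra <- r - minimum * k
  share <- extra * w / sum(w)
  base <- floor(share)
  rem <- extra - sum(base)
  if (rem > 0) {
    ord <- order(-(share - base), seq_len(k))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(minimum + base)
}

# Spare (implicit-hydrogen) valence per atom of a graph; charged atoms and
# exotic elements report 0 so decoration leaves them untouched.
#' @noRd
spare_valence <- function(g) {
  bsum <- numeric(length(g$el))
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      bsum[g$bonds[b, 1]] <- bsum[g$bonds[b, 1]] + g$bonds[b, 3]
      bsum[g$bonds[b, 2]] <- bsum[g$bonds[b, 2]] + g$bonds[b, 3]
    }
  }
  val <- .DEFAULT_VALENCE[g$el]
  val[is.na(val)] <- 0L
  spare <- val - bsum
  spare[g$chg != 0L] <- 0
  pmax(spare, 0)
}

# Attach 1-3 random acyclic substituents to a scaffold graph; returns a
# molblock. Substituents are single-bonded trees, so the GNB scaffold of
# the decorated molecule is the scaffold itself.
#' @noRd
decorate_scaffold <- function(g) {
  el <- g$el
  chg <- g$chg
  bonds <- g$bonds
  nsub <- sample.int(3L, 1L)
  for (s in seq_len(nsub)) {
    spare <- spare_valence(list(el = el, chg = chg, bonds = bonds))
    cand <- which(spare >= 1)
    if (!length(cand)) break
    at <- sample1(cand)
    chain <- .SUBSTITUENTS[[sample.int(length(.SUBSTITUENTS), 1L)]]
    prev <- at
    for (a in chain) {
      el <- c(el, a)
      chg <- c(chg, 0L)
      bonds <- rbind(bonds, c(prev, length(el), 1L))
      prev <- length(el)
    }
  }
  build_molblock(el, chg, bonds)
}

# Random acyclic molecule: a linear heavy-atom chain with mostly carbon
# and occasional ether/amine heteroatoms.
#' @noRd
random_acyclic_smiles <- function() {
  len <- sample(3:10, 1L)
  el <- c("C", sample(c("C", "C", "C", "C", "O", "N"), len - 2L,
                      replace = TRUE), "C")
  paste(el, collapse = "")
}

#' Generate a synthetic chemical library
#'
#' Builds a library matching a [synthetic_spec()]: cyclic molecules are
#' made by decorating scaffolds drawn from the built-in vocabulary (see
#' [scaffold_vocabulary()]) with randomized acyclic substituents, so the
#' GNB scaffold of every emitted molecule equals its assigned scaffold;
#' acyclic molecules are randomized heteroatom chains. Scaffold
#' frequencies follow a Zipf law with the requested exponent, subject to
#' the singleton constraint (singleton scaffolds get exactly one molecule,
#' all others at least two). All SMILES are canonical, stereo-free,
#' pairwise distinct, and survive [clean_and_deduplicate()] unchanged.
#'
#' @param spec a [synthetic_spec()].
#' @param name library name (default derived from the seed).
#' @param vocabulary optional custom scaffold vocabulary (canonical GNB
#'   keys).
#' @return list with `library` (a [chem_library()]) and `ground_truth`
#'   (list: `assignment` data.frame `id`/`scaffold_key`, `counts` named
#'   vector, `N`, `N_sing`, `spec`).
#' @export
generate_library <- function(spec, name = NULL, vocabulary = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  vocab <- vocabulary %||% scaffold_vocabulary()
  name <- name %||% sprintf("synth_seed%d", spec$seed)
  n_acyclic <- round(spec$acyclic_fraction * spec$M)
  n_cyclic <- spec$M - n_acyclic
  if (spec$n_scaffolds > n_cyclic)
    stop("infeasible spec: n_scaffolds exceeds the number of cyclic molecules")
  if (spec$n_scaffolds > length(vocab))
    stop("infeasible spec: vocabulary has only ", length(vocab), " scaffolds")
  n_sing <- round(spec$singleton_fraction * spec$n_scaffolds)
  n_pop <- spec$n_scaffolds - n_sing
  r <- n_cyclic - n_sing
  if (n_pop == 0L && r != 0L)
    stop("infeasible spec: all scaffolds are singletons but M leaves ",
         r, " extra cyclic molecules")
  if (n_pop > 0L && r < 2L * n_pop)
    stop("infeasible spec: non-singleton scaffolds need at least 2 ",
         "molecules each")

  with_seed(spec$seed, {
    keys <- sample(vocab, spec$n_scaffolds)
    counts <- c(if (n_pop > 0L) zipf_allocation(r, n_pop, spec$skew),
                rep(1L, n_sing))
    smiles <- character(0)
    scaffold_of <- character(0)
    for (i in seq_along(keys)) {
      key <- keys[i]
      grp <- key                       # bare scaffold is the first member
      if (counts[i] > 1L) {
        g <- mol_graph(smiles_to_sdf(key)[[1]])
        tries <- 0L
        while (length(grp) < counts[i]) {
          need <- counts[i] - length(grp)
          mbs <- replicate(need, decorate_scaffold(g))
          cand <- molblocks_to_smiles(mbs)
          grp <- unique(c(grp, cand))
          tries <- tries + 1L
          if (tries > 100L)
            stop("infeasible spec: cannot place ", counts[i],
                 " distinct decorations on scaffold ", key)
        }
      }
      smiles <- c(smiles, grp)
      scaffold_of <- c(scaffold_of, rep(key, counts[i]))
    }
    if (n_acyclic > 0L) {
      acy <- character(0)
      tries <- 0L
      while (length(acy) < n_acyclic) {
        cand <- ob_canonical(replicate(n_acyclic - length(acy),
                                       random_acyclic_smiles()))
        acy <- unique(c(acy, cand[!is.na(cand)]))
        tries <- tries + 1L
        if (tries > 100L) stop("cannot generate distinct acyclic molecules")
      }
      smiles <- c(smiles, acy)
      scaffold_of <- c(scaffold_of, rep(ACYCLIC_TOKEN, n_acyclic))
    }
    ord <- sample.int(length(smiles))
    smiles <- smiles[ord]
    scaffold_of <- scaffold_of[ord]
    ids <- sprintf("%s_%05d", name, seq_along(smiles))
    lib <- chem_library(name, ids, smiles)
    tab <- table(scaffold_of)
    gt_counts <- stats::setNames(as.integer(tab), names(tab))
    list(library = lib,
         ground_truth = list(
           assignment = data.frame(id = ids, scaffold_key = scaffold_of,
                                   stringsAsFactors = FALSE),
           counts = gt_counts,
           N = length(gt_counts),
           N_sing = sum(gt_counts == 1L),
           spec = spec))
  })
}
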