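# Bemis-Murcko scaffold computation at the three Lipkus abstraction levels
# and per-library scaffold frequency tables.

#' Reserved scaffold key for molecules without rings
#'
#' All acyclic molecules share one pseudo-scaffold so that they participate
#' in scaffold statistics (N, N_sing, CSR curves, entropies) like any other
#' scaffold.
#' @export
ACYCLIC_TOKEN <- "ACYCLIC"

.LEVELS <- c("GNB", "GN", "GRAPH")

# Iteratively prune terminal (degree <= 1) atoms: what remains is the union
# of all rings and the linker paths connecting them (the Murcko framework,
# i.e. the 2-core of the molecular graph).
#' @noRd
framework_atoms <- function(n, bonds) {
  if (n == 0L || nrow(bonds) == 0L) return(integer(0))
  keep <- rep(TRUE, n)
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), n)
  repeat {
    term <- which(keep & deg <= 1L)
    if (!length(term)) break
    keep[term] <- FALSE
    drop1 <- bonds[, 1] %in% term & keep[bonds[, 2]]
    drop2 <- bonds[, 2] %in% term & keep[bonds[, 1]]
    if (any(drop1)) {
      d <- tabulate(bonds[drop1, 2], n)
      deg <- deg - d
    }
    if (any(drop2)) {
      d <- tabulate(bonds[drop2, 1], n)
      deg <- deg - d
    }
    deg[term] <- 0L
  }
  which(keep)
}

# Scaffold molblock of one molecule graph at a given level, or NULL when the
# molecule is acyclic. At GNB, terminal atoms attached to the framework by a
# double or triple bond (e.g. exocyclic carbonyl oxygens) are retained, as in
# the usual Bemis-Murcko framework convention. At GN/GRAPH all bonds collapse
# to single order first, so those atoms become prunable side chains and the
# resulting keys are idempotent at their level.
#' @noRd
scaffold_molblock <- function(g, level) {
  core <- framework_atoms(length(g$el), g$bonds)
  if (!length(core)) return(NULL)
  keep <- logical(length(g$el))
  keep[core] <- TRUE
  if (level == "GNB") {
    o2 <- g$bonds[, 3] >= 2L
    extra <- c(g$bonds[o2 & keep[g$bonds[, 1]] & !keep[g$bonds[, 2]], 2],
               g$bonds[o2 & keep[g$bonds[, 2]] & !keep[g$bonds[, 1]], 1])
    keep[extra] <- TRUE
  }
  idx <- which(keep)
  map <- integer(length(g$el))
  map[idx] <- seq_along(idx)
  bsel <- g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], , drop = FALSE]
  el <- g$el[idx]
  chg <- g$chg[idx]
  bonds <- cbind(map[bsel[, 1]], map[bsel[, 2]], bsel[, 3])
  if (level %in% c("GN", "GRAPH")) bonds[, 3] <- 1L
  if (level == "GRAPH") {
    el[] <- "C"
    chg[] <- 0L
  }
  build_molblock(el, chg, bonds)
}

#' Compute Bemis-Murcko scaffolds
#'
#' The scaffold of a cyclic molecule is its set of ring systems plus the
#' linkers connecting them, obtained by iteratively pruning terminal
#' side-chain atoms. Three abstraction levels are supported:
#'
#' * `"GNB"` (graph/node/bond): elements and bond orders retained; terminal
#'   atoms double- or triple-bonded to the framework (exocyclic carbonyls
#'   and the like) stay attached.
#' * `"GN"` (graph/node): elements retained, every bond reduced to single
#'   order.
#' * `"GRAPH"`: every atom mutated to carbon and every bond to single order
#'   (the anonymous ring skeleton).
#'
#' Acyclic molecules have no scaffold in the Bemis-Murcko sense and are
#' assigned the shared pseudo-scaffold [ACYCLIC_TOKEN] at every level.
#' Scaffold keys are canonical SMILES, so re-deriving the scaffold of a key
#' returns the key itself.
#'
#' @param smiles character vector of SMILES strings.
#' @param level scaffold abstraction level, one of `"GNB"`, `"GN"`,
#'   `"GRAPH"`. Default `"GNB"`, the most informative level and the one used
#'   for the diversity metrics.
#' @return character vector of scaffold keys (canonical SMILES or
#'   `"ACYCLIC"`), one per input molecule.
#' @examples
#' \dontrun{
#' compute_scaffold("Cc1ccccc1")            # "c1ccccc1"
#' compute_scaffold("CCO")                  # "ACYCLIC"
#' compute_scaffold("c1ccncc1", "GRAPH")    # "C1CCCCC1"
#' }
#' @export
compute_scaffold <- function(smiles, level = c("GNB", "GN", "GRAPH")) {
  level <- match.arg(level)
  if (!length(smiles)) return(character(0))
  sdf <- tryCatch(smiles_to_sdf(smiles),
                  error = function(e) stop("unparseable SMILES input: ",
                                           conditionMessage(e)))
  if (length(sdf) != length(smiles)) stop("unparseable SMILES input")
  keys <- rep(ACYCLIC_TOKEN, length(smiles))
  molblocks <- character(0)
  which_cyclic <- integer(0)
  for (i in seq_along(smiles)) {
    mb <- scaffold_molblock(mol_graph(sdf[[i]]), level)
    if (!is.null(mb)) {
      molblocks <- c(molblocks, mb)
      which_cyclic <- c(which_cyclic, i)
    }
  }
  if (length(which_cyclic)) {
    keys[which_cyclic] <- molblocks_to_smiles(molblocks)
  }
  keys
}

#' Scaffold frequency table of a library
#'
#' Aggregates [compute_scaffold()] over all records of a cleaned library.
#' All acyclic molecules pool into the single `"ACYCLIC"` pseudo-scaffold,
#' which is counted in `N` and may be a singleton like any other scaffold.
#'
#' @param lib a cleaned, deduplicated [chem_library()].
#' @param level scaffold abstraction level (see [compute_scaffold()]).
#' @return A `ScaffoldCounts` object: list with `library_name`, `level`,
#'   `counts` (named integer vector, scaffold key -> number of molecules),
#'   `assignment` (data.frame `id`, `scaffold_key`), `M` (molecules), `N`
#'   (distinct scaffolds), `N_sing` (scaffolds with exactly one molecule).
#' @export
scaffold_counts <- function(lib, level = c("GNB", "GN", "GRAPH")) {
  stopifnot(inherits(lib, "ChemLibrary"))
  level <- match.arg(level)
  keys <- compute_scaffold(lib$records$smiles, level)
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(
    list(library_name = lib$name,
         level = level,
         counts = counts,
         assignment = data.frame(id = lib$records$id, scaffold_key = keys,
                                 stringsAsFactors = FALSE),
         M = length(keys),
         N = length(counts),
         N_sing = sum(counts == 1L)),
    class = "ScaffoldCounts")
}

#' Build a ScaffoldCounts object from a bare frequency table
#'
#' Useful for analytic checks and for downstream metrics when the
#' scaffold-to-molecule assignment is already known.
#'
#' @param counts named integer vector (scaffold key -> molecule count).
#' @param library_name library tag.
#' @param level scaffold level tag.
#' @return A `ScaffoldCounts` object (without per-molecule assignment).
#' @export
scaffold_counts_from_table <- function(counts, library_name = "library",
                                       level = "GNB") {
  stopifnot(length(counts) >= 1L, all(counts >= 1))
  if (is.null(names(counts))) names(counts) <- paste0("S", seq_along(counts))
  v <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(library_name = library_name, level = level, counts = v,
         assignment = NULL, M = sum(v), N = length(v),
         N_sing = sum(v == 1L)),
    class = "ScaffoldCounts")
}

#' @export
print.ScaffoldCounts <- function(x, ...) {
  cat(sprintf("<ScaffoldCounts> %s [%s]: M=%d, N=%d, N_sing=%d\n",
              x$library_name, x$level, x$M, x$N, x$N_sing))
  invisible(x)
}

#' Write a scaffold frequency table as TSV
#'
#' Columns: `level`, `scaffold_key`, `count`, `is_singleton`, sorted by
#' descending count then key.
#'
#' @param sc a `ScaffoldCounts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_table <- function(sc, path) {
  stopifnot(inherits(sc, "ScaffoldCounts"))
  ord <- order(-sc$counts, names(sc$counts))
  df <- data.frame(level = sc$level,
                   scaffold_key = names(sc$counts)[ord],
                   count = as.integer(sc$counts[ord]),
                   is_singleton = sc$counts[ord] == 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
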