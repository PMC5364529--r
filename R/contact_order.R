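#' Relative contact order from atomic coordinates
#'
#' `RCO = (1/(L N)) sum_contacts |i - j|` where the sum runs over all
#' qualifying heavy-atom pairs: inter-atomic distance within `cutoff` and
#' residue separation `|i - j| >= min_separation`. Each qualifying atom pair
#' contributes one contact (`N` = number of such pairs); `L` is the number
#' of resolved residues. Residues are renumbered 1..L in chain order after
#' gap compaction.
#'
#' @param coordinates A path to a PDB/mmCIF file, a `bio3d` `pdb` object, or
#'   a data frame with columns `resno`, `x`, `y`, `z` (heavy atoms only).
#' @param cutoff Contact distance cutoff, Angstrom (default 6).
#' @param min_separation Minimum residue separation |i - j| (default 2).
#' @param chain Chain identifier; required when the file holds several
#'   chains.
#' @return List with `rco`, `n_contacts`, `n_residues`, and the `contacts`
#'   data frame (`i`, `j`, `separation`, per qualifying atom pair).
#' @examples
#' # toy chain: 10 residues, one qualifying atom pair between residues 2 and 7
#' xyz <- data.frame(resno = 1:10, x = c(1:10) * 10, y = 0, z = 0)
#' xyz$x[7] <- xyz$x[2] + 3  # bring residues 2 and 7 within 6 A
#' relative_contact_order(xyz)$rco # 5 / (10 * 1) = 0.5
#' @export
relative_contact_order <- function(coordinates, cutoff = 6,
                                   min_separation = 2, chain = NULL) {
  atoms <- contact_order_atoms(coordinates, chain)
  if (length(unique(atoms$resno)) < 3L) stop("need at least 3 resolved residues")
  # gap-compacted 1-based residue index
  res_levels <- unique(atoms$resno)
  idx <- match(atoms$resno, res_levels)
  L <- length(res_levels)

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  contacts <- vector("list", n)
  cutoff2 <- cutoff^2
  for (a in seq_len(n - 1L)) {
    b <- (a + 1L):n
    sep <- abs(idx[b] - idx[a])
    cand <- b[sep >= min_separation]
    if (!length(cand)) next
    d2 <- (xyz[cand, 1L] - xyz[a, 1L])^2 + (xyz[cand, 2L] - xyz[a, 2L])^2 +
      (xyz[cand, 3L] - xyz[a, 3L])^2
    hit <- cand[d2 <= cutoff2]
    if (length(hit)) {
      contacts[[a]] <- data.frame(i = idx[a], j = idx[hit],
                                  separation = abs(idx[hit] - idx[a]))
    }
  }
  contacts <- do.call(rbind, contacts)
  if (is.null(contacts) || nrow(contacts) == 0L) {
    stop("no qualifying contacts under this cutoff/separation convention")
  }
  swap <- contacts$i > contacts$j
  tmp <- contacts$i[swap]; contacts$i[swap] <- contacts$j[swap]; contacts$j[swap] <- tmp
  n_contacts <- nrow(contacts)
  rco <- sum(contacts$separation) / (L * n_contacts)
  list(rco = rco, n_contacts = n_contacts, n_residues = L, contacts = contacts)
}

contact_order_atoms <- function(coordinates, chain = NULL) {
  if (is.data.frame(coordinates)) {
    stopifnot(all(c("resno", "x", "y", "z") %in% names(coordinates)))
    return(coordinates[, c("resno", "x", "y", "z")])
  }
  pdb <- if (inherits(coordinates, "pdb")) {
    coordinates
  } else if (is.character(coordinates)) {
    if (grepl("\\.cif$", coordinates, ignore.case = TRUE)) {
      bio3d::read.cif(coordinates)
    } else {
      bio3d::read.pdb(coordinates)
    }
  } else {
    stop("unsupported coordinate input")
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop("multi-chain structure: select one with `chain=` (found: ",
           paste(chains, collapse = ", "), ")")
    }
  } else {
    at <- at[at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0L) stop("chain not found: ", chain)
  }
  # heavy atoms only
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1L, 1L)
  }
  at <- at[!(toupper(trimws(elem)) %in% c("H", "D")), , drop = FALSE]
  data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z)
}
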