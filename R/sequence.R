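## Building cylinder models of linear polyelectrolytes from sequences.

#' Default pKa and geometry table
#'
#' Loads the ionization-constant and geometry defaults shipped with the
#' package (a YAML file under `extdata`): per-residue pKa values and
#' valences, the default ionized-group radius, and per-kind cylinder
#' geometry (diameter and contour rise per residue/base).
#'
#' @param path optional path to an alternative YAML table with the same
#'   structure.
#' @return nested list with elements `ion_radius_nm`, `groups`, `geometry`.
#' @export
default_pka_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_defaults.yaml", package = "pbcharge",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

## residue letter -> group key
.aa_group_key <- c(D = "ASP", E = "GLU", C = "CYS", Y = "TYR",
                   K = "LYS", R = "ARG", H = "HIS")
.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a cylinder model from a sequence
#'
#' Counts the ionizable residues (plus termini, for proteins) or
#' phosphates of a linear molecule and returns a [cylinder_model()] with
#' those groups spread uniformly over its surface. Polypeptides,
#' single-stranded and double-stranded nucleic acids become rigid hollow
#' cylinders of diameter 0.5, 1 and 2 nm respectively, with lengths set by
#' full extension of the chain (0.38 nm per residue, 0.34 nm per
#' base or base pair; configurable through the table).
#'
#' @param sequence character string of one-letter residue codes (protein)
#'   or bases (nucleic acids; for dsDNA give one strand -- two phosphates
#'   per base pair are counted).
#' @param kind `"protein"`, `"ssDNA"` or `"dsDNA"`.
#' @param pka_table a table from [default_pka_table()].
#' @param termini for proteins, include N/C terminal groups (default TRUE).
#' @return A [cylinder_model()] with `surface_groups` filled in.
#' @export
#' @examples
#' m <- build_from_sequence("EEEE", "protein")
#' structural_charge(m$surface_groups, pH = 7)
build_from_sequence <- function(sequence, kind = c("protein", "ssDNA", "dsDNA"),
                                pka_table = default_pka_table(),
                                termini = TRUE) {
  kind <- match.arg(kind)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) == 0) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  geo <- pka_table$geometry[[kind]]
  rA <- pka_table$ion_radius_nm
  mk <- function(key, count) {
    g <- pka_table$groups[[key]]
    list(group = ionizable_group(g$pKa, g$valence, rA, label = key),
         count = count)
  }
  if (kind == "protein") {
    bad <- which(!chars %in% .aa_alphabet)
    if (length(bad))
      stop("unknown residue code(s) at position(s) ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(chars[bad]), collapse = ""), call. = FALSE)
    tab <- table(chars)
    ent <- list()
    for (aa in names(.aa_group_key)) {
      n <- if (aa %in% names(tab)) as.integer(tab[[aa]]) else 0L
      if (n > 0) ent <- c(ent, list(mk(.aa_group_key[[aa]], n)))
    }
    if (termini)
      ent <- c(ent, list(mk("NTERM", 1), mk("CTERM", 1)))
    if (length(ent) == 0)
      stop("sequence carries no ionizable groups", call. = FALSE)
  } else {
    alphabet <- if (kind == "ssDNA") c("A", "C", "G", "T", "U")
                else c("A", "C", "G", "T")
    bad <- which(!chars %in% alphabet)
    if (length(bad))
      stop("unknown base(s) at position(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    nphos <- length(chars) * geo$phosphates_per_unit
    ent <- list(mk("PHOSPHATE", nphos))
  }
  gs <- group_set(lapply(ent, `[[`, "group"),
                  vapply(ent, `[[`, 0, "count"))
  cylinder_model(radius = geo$diameter_nm / 2,
                 length = length(chars) * geo$rise_nm,
                 surface_groups = gs)
}

#' Append extra ionizable or permanent charges to a model
#'
#' Adds additional groups (for example fluorescent dye moieties) to a
#' model's inventory. A permanent charge is encoded as a group titrating
#' far outside the experimental pH window (pKa near 0 for a permanent
#' negative charge, near 14 for a permanent positive one).
#'
#' @param model a [cylinder_model()] or [sphere_model()] with groups.
#' @param extra data.frame (or list of lists) with columns/fields
#'   `count`, `pKa`, `valence` (and optionally `label`, `ion_radius`).
#' @return the model with the enlarged group set.
#' @export
add_extra_charges <- function(model, extra) {
  if (is.null(extra) || (is.data.frame(extra) && nrow(extra) == 0))
    return(model)
  if (is.data.frame(extra)) extra <- split(extra, seq_len(nrow(extra)))
  slot <- if (inherits(model, "cylinder_model")) "surface_groups" else "groups"
  gs <- model[[slot]]
  for (e in extra) {
    g <- ionizable_group(e$pKa, e$valence,
                         if (!is.null(e$ion_radius)) e$ion_radius else 0.25,
                         if (!is.null(e$label)) e$label else "extra")
    gs$groups <- c(gs$groups, list(g))
    gs$counts <- c(gs$counts, e$count)
  }
  model[[slot]] <- group_set(gs$groups, gs$counts)
  model
}

#' Read a (possibly line-wrapped) FASTA file
#'
#' Thin wrapper around [seqinr::read.fasta()] returning plain character
#' strings keyed by record name.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, seqonly = FALSE,
                             forceDNAtolower = FALSE)
  out <- vapply(recs, function(r) toupper(as.character(r)[1]), "")
  names(out) <- names(recs)
  out
}
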