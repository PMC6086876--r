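# Atom selection mini-language.
#
# Grammar (conjunctions and unions only; "and" binds tighter than "or"):
#   expr  := group (" or " group)*
#   group := term (" and " term)*
#   term  := "all" | "protein" | "substrate" | "hetero"
#          | "resid"   <ranges>   e.g. resid 138-140  /  resid 1,5,9-12
#          | "resname" <list>     e.g. resname PLP,PLM
#          | "chain"   <list>     e.g. chain A,B
#          | "type"    <list>     e.g. type AHA-like
#
# Evaluation against a structure yields a deterministic, ascending atom index
# vector. "protein" means ATOM records with substrate_type "none"; "substrate"
# means substrate_type != "none".

parse_int_ranges <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
      m <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
      out <- c(out, seq(as.integer(m[2]), as.integer(m[3])))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("cannot parse residue range: '", p, "'")
    }
  }
  out
}

eval_term <- function(term, atoms) {
  term <- trimws(term)
  if (term == "all") return(rep(TRUE, nrow(atoms)))
  if (term == "protein")
    return(atoms$record == "ATOM" & atoms$substrate_type == "none")
  if (term == "substrate") return(atoms$substrate_type != "none")
  if (term == "hetero") return(atoms$record == "HETATM")
  m <- regmatches(term, regexec("^(resid|resname|chain|type)\\s+(.+)$", term))[[1]]
  if (length(m) == 0) stop("cannot parse selection term: '", term, "'")
  value <- trimws(m[3])
  switch(m[2],
    resid   = atoms$residue_number %in% parse_int_ranges(value),
    resname = atoms$residue_name %in% trimws(strsplit(value, ",")[[1]]),
    chain   = atoms$chain_id %in% trimws(strsplit(value, ",")[[1]]),
    type    = atoms$substrate_type %in% trimws(strsplit(value, ",")[[1]])
  )
}

#' Select atoms of a structure
#'
#' Evaluates a selection expression (see Details) against a structure and
#' returns the matching atom indices, always in ascending order so selections
#' are deterministic.
#'
#' @details Terms: `all`, `protein`, `substrate`, `hetero`,
#'   `resid 138-140`, `resname PLP,PLM`, `chain A`, `type AHA-like`.
#'   Terms combine with `and` (intersection) and `or` (union); `and` binds
#'   tighter. Example: `"protein and resid 138-140"`.
#'
#' @param structure an `sc_structure`
#' @param expression selection string
#' @return integer vector of atom indices (possibly empty)
#' @export
#' @examples
#' # select_atoms(structure, "protein and resid 138-140")
select_atoms <- function(structure, expression) {
  atoms <- structure$atoms
  groups <- strsplit(expression, "\\s+or\\s+")[[1]]
  keep <- rep(FALSE, nrow(atoms))
  for (g in groups) {
    terms <- strsplit(g, "\\s+and\\s+")[[1]]
    gk <- rep(TRUE, nrow(atoms))
    for (t in terms) gk <- gk & eval_term(t, atoms)
    keep <- keep | gk
  }
  which(keep)
}
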