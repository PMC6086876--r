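# Active-site arrival detection. A site is anchored on a cofactor atom
# selection (e.g. PLP in the "empty" monomer, the PLP-aldimine in the
# "occupied" one); a substrate molecule "arrives" at the first frame its
# centroid comes within hydrogen-bonding distance of the nearest anchor atom,
# and is tracked thereafter for retention within a looser site region.

#' Define an active site
#'
#' @param site_id label, e.g. `"empty"` or `"occupied"`
#' @param anchor_sel selection string for the anchor atoms (typically the
#'   cofactor, e.g. `"resname PLP"`)
#' @param arrival_cutoff arrival distance in Angstrom, default 3.5 (a typical
#'   donor-acceptor hydrogen-bond heavy-atom distance)
#' @param site_region_cutoff retention-accounting distance, default 6;
#'   must be >= `arrival_cutoff`
#' @return object of class `sc_site`
#' @export
site_definition <- function(site_id, anchor_sel, arrival_cutoff = 3.5,
                            site_region_cutoff = 6) {
  if (arrival_cutoff <= 0 || arrival_cutoff > site_region_cutoff)
    stop("require 0 < arrival_cutoff <= site_region_cutoff")
  structure(list(site_id = site_id, anchor_sel = anchor_sel,
                 arrival_cutoff = arrival_cutoff,
                 site_region_cutoff = site_region_cutoff),
            class = "sc_site")
}

#' Detect active-site arrivals of substrate molecules
#'
#' For every molecule x site, finds the first frame at which the molecule
#' centroid lies within `arrival_cutoff` of the nearest site anchor atom
#' (`NA` if never), and the retention fraction: the fraction of frames from
#' the arrival frame onward spent within `site_region_cutoff`. The window
#' includes the arrival frame itself, so retention is always defined and
#' positive for an arriving molecule; a molecule pinned at the site for the
#' whole run has retention 1.
#'
#' @param series an [sc_centroid_series()] (post-alignment frame of
#'   `structure`)
#' @param structure reference [sc_structure()] containing the anchors
#' @param sites list of [site_definition()] (a single site is accepted)
#' @param replicate optional replicate label attached to every record
#' @return data.frame of class `sc_arrivals`: `replicate`, `molecule_tag`,
#'   `substrate_type`, `site_id`, `first_arrival_frame`, `retention_fraction`
#' @export
detect_arrivals <- function(series, structure, sites, replicate = NA) {
  if (inherits(sites, "sc_site")) sites <- list(sites)
  df <- as.data.frame(series)
  mols <- unique(df[, c("molecule_tag", "substrate_type")])
  out <- list()
  for (site in sites) {
    idx <- select_atoms(structure, site$anchor_sel)
    if (!length(idx))
      stop("site '", site$site_id, "': anchor selection matches no atoms ('",
           site$anchor_sel, "')")
    ra <- coords(structure)[idx, , drop = FALSE]
    d2min <- rep(Inf, nrow(df))
    for (r in seq_len(nrow(ra))) {
      d2 <- (df$x - ra[r, 1])^2 + (df$y - ra[r, 2])^2 + (df$z - ra[r, 3])^2
      d2min <- pmin(d2min, d2)
    }
    d <- sqrt(d2min)
    for (m in seq_len(nrow(mols))) {
      rows <- which(df$molecule_tag == mols$molecule_tag[m])
      rows <- rows[order(df$frame[rows])]
      hit <- d[rows] <= site$arrival_cutoff
      if (any(hit)) {
        first <- which(hit)[1]
        after <- rows[first:length(rows)]
        retention <- mean(d[after] <= site$site_region_cutoff)
        fa <- df$frame[rows[first]]
      } else {
        fa <- NA_integer_; retention <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        replicate = replicate, molecule_tag = mols$molecule_tag[m],
        substrate_type = mols$substrate_type[m], site_id = site$site_id,
        first_arrival_frame = fa, retention_fraction = retention,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sc_arrivals", "data.frame")
  res
}

#' Count replicates in which a substrate reached each site
#'
#' Given arrival records labelled by replicate, counts per site the number of
#' replicates with at least one arrival of the given substrate type, and the
#' overall fraction of replicates with any arrival at any site.
#'
#' @param records an `sc_arrivals` data.frame (rows from several replicates,
#'   `replicate` column filled)
#' @param substrate_type optional filter, e.g. `"AHA-like"`
#' @return list with `counts` (data.frame `site_id`, `n_reaching`),
#'   `n_replicates`, `fraction_any`
#' @export
count_reaching_replicates <- function(records, substrate_type = NULL) {
  df <- as.data.frame(records)
  reps <- unique(df$replicate)
  if (!is.null(substrate_type)) df <- df[df$substrate_type == substrate_type, ]
  arrived <- df[!is.na(df$first_arrival_frame), ]
  sites <- unique(as.data.frame(records)$site_id)
  counts <- data.frame(
    site_id = sites,
    n_reaching = vapply(sites, function(s)
      length(unique(arrived$replicate[arrived$site_id == s])), integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  frac <- if (length(reps)) length(unique(arrived$replicate)) / length(reps) else 0
  list(counts = counts, n_replicates = length(reps), fraction_any = frac)
}

#' Restrict a centroid series to molecules that reached a site
#'
#' Channel structure emerges when clustering is run on only the molecules
#' that ultimately travelled into an active site; this filter produces that
#' subset. With `site_id` given, only molecules arriving at that site are
#' kept (enabling per-site colouring of the resulting clusters).
#'
#' @param series an [sc_centroid_series()]
#' @param records arrival records computed from the same series
#' @param site_id optional site restriction
#' @return an [sc_centroid_series()] subset (idempotent; empty when nothing
#'   arrived)
#' @export
filter_arriving <- function(series, records, site_id = NULL) {
  df <- as.data.frame(records)
  if (!is.null(site_id)) df <- df[df$site_id == site_id, ]
  tags <- unique(df$molecule_tag[!is.na(df$first_arrival_frame)])
  sc_centroid_series(as.data.frame(series)[series$molecule_tag %in% tags, ])
}

#' Write arrival records as CSV
#' @param records an `sc_arrivals` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_arrivals <- function(records, path) {
  df <- as.data.frame(records)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("replicate,molecule_tag,substrate_type,site_id,first_arrival_frame,retention_fraction", con, sep = "\n")
  if (nrow(df))
    writeLines(sprintf("%s,%s,%s,%s,%s,%s",
                       ifelse(is.na(df$replicate), "", as.character(df$replicate)),
                       df$molecule_tag, df$substrate_type, df$site_id,
                       ifelse(is.na(df$first_arrival_frame), "",
                              as.character(df$first_arrival_frame)),
                       ifelse(is.na(df$retention_fraction), "",
                              sprintf("%.6f", df$retention_fraction))),
               con, sep = "\n")
  invisible(path)
}
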