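## protein_annotation: domain architecture, binding-site registry and
## per-residue structural environment, with interval/proximity queries.

#' Load a protein annotation file
#'
#' The annotation is structured text (YAML) with fields `protein`, `length`,
#' `domains` (each with `name` and either `start`/`end` or a `segments` list
#' for discontinuous domains) and `binding_sites` (each with `name`,
#' `host_domain` and `residues` and/or `intervals`). Intervals are 1-based
#' and inclusive. An optional per-residue environment table (TSV with
#' columns `position`, `location_class`, `bh`, `rsa`) can be attached.
#'
#' Validation rejects segments with `start > end`, overlapping same-level
#' domain segments, and binding-site residues outside their host domain.
#' Point queries run on a sorted interval index (logarithmic lookup).
#'
#' @param path YAML annotation file.
#' @param environment Optional path to the per-residue environment TSV.
#' @return A `protein_annotation` object.
#' @export
load_annotation <- function(path, environment = NULL) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$length) || spec$length < 1) {
    abort("annotation must declare a positive protein length",
          class = "mutriage_error_annotation")
  }
  segs <- bind_rows(lapply(spec$domains, function(d) {
    if (!is.null(d$segments)) {
      bind_rows(lapply(d$segments, function(s) {
        tibble(name = d$name, seg_start = as.integer(s[[1]]),
               seg_end = as.integer(s[[2]]))
      }))
    } else {
      tibble(name = d$name, seg_start = as.integer(d$start),
             seg_end = as.integer(d$end))
    }
  }))
  if (any(segs$seg_start > segs$seg_end)) {
    abort("domain segment with start > end", class = "mutriage_error_annotation")
  }
  ir <- IRanges::IRanges(segs$seg_start, segs$seg_end, names = segs$name)
  ov <- IRanges::findOverlaps(ir, ir)
  if (length(ov) > length(ir)) {
    abort("overlapping domain segments in annotation",
          class = "mutriage_error_annotation")
  }
  sites <- bind_rows(lapply(spec$binding_sites, function(s) {
    rows <- list()
    if (!is.null(s$residues)) {
      rows <- c(rows, list(tibble(site = s$name, host_domain = s$host_domain,
                                  start = as.integer(unlist(s$residues)),
                                  end = as.integer(unlist(s$residues)))))
    }
    if (!is.null(s$intervals)) {
      rows <- c(rows, list(bind_rows(lapply(s$intervals, function(iv) {
        tibble(site = s$name, host_domain = s$host_domain,
               start = as.integer(iv[[1]]), end = as.integer(iv[[2]]))
      }))))
    }
    bind_rows(rows)
  }))
  ann <- structure(
    list(protein = spec$protein %||% "protein",
         length = as.integer(spec$length),
         domains = segs,
         domain_index = ir,
         sites = sites,
         site_index = if (nrow(sites) > 0)
           IRanges::IRanges(sites$start, sites$end, names = sites$site)
         else IRanges::IRanges(),
         environment = NULL),
    class = "protein_annotation")
  ## binding-site residues must lie inside their host domain's segments
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      host <- segs[segs$name == sites$host_domain[i], , drop = FALSE]
      inside <- any(sites$start[i] >= host$seg_start &
                    sites$end[i] <= host$seg_end)
      if (nrow(host) == 0 || !inside) {
        abort(sprintf("binding site '%s' residues %d-%d outside host domain '%s'",
                      sites$site[i], sites$start[i], sites$end[i],
                      sites$host_domain[i]),
              class = "mutriage_error_annotation")
      }
    }
  }
  if (!is.null(environment)) {
    ann$environment <- load_environment(environment)
  }
  ann
}

#' Load a per-residue environment table
#'
#' TSV with columns `position`, `location_class` (`buried`/`surface`), `bh`
#' (0/1 between-helices flag) and optional `rsa` in \[0,1\]. Comment lines
#' start with `#`.
#'
#' @param path TSV file.
#' @export
load_environment <- function(path) {
  env <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         na = c("", "NA"))
  need <- c("position", "location_class", "bh")
  missing_cols <- setdiff(need, names(env))
  if (length(missing_cols) > 0) {
    abort(sprintf("environment table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "mutriage_error_annotation")
  }
  if (!"rsa" %in% names(env)) env$rsa <- NA_real_
  bad <- !is.na(env$location_class) &
    !(env$location_class %in% c("buried", "surface"))
  if (any(bad)) {
    abort("location_class must be 'buried' or 'surface'",
          class = "mutriage_error_annotation")
  }
  env$position <- as.integer(env$position)
  env$bh <- as.integer(env$bh)
  env$rsa <- as.numeric(env$rsa)
  env
}

#' @export
print.protein_annotation <- function(x, ...) {
  cat("<protein_annotation>", x$protein, "\n",
      " length:", x$length, "residues\n",
      " domains:", length(unique(x$domains$name)),
      sprintf("(%d segments)", nrow(x$domains)), "\n",
      " binding sites:", length(unique(x$sites$site)), "\n",
      " environment table:",
      if (is.null(x$environment)) "none" else
        sprintf("%d positions", nrow(x$environment)), "\n")
  invisible(x)
}

#' Locate the domain containing a residue
#'
#' Returns the name of the deepest (narrowest) domain segment containing
#' each position, or `"inter-domain"` for annotated-protein positions in no
#' domain.
#'
#' @param position Integer vector of residue positions.
#' @param annotation A `protein_annotation`.
#' @return Character vector of domain names.
#' @export
locate_domain <- function(position, annotation) {
  stopifnot(inherits(annotation, "protein_annotation"))
  position <- as.integer(position)
  if (any(position < 1L | position > annotation$length)) {
    abort("position outside the annotated sequence range",
          class = "mutriage_error_annotation")
  }
  q <- IRanges::IRanges(position, position)
  hits <- IRanges::findOverlaps(q, annotation$domain_index)
  out <- rep("inter-domain", length(position))
  if (length(hits) > 0) {
    h <- tibble(q = S4Vectors::queryHits(hits),
                s = S4Vectors::subjectHits(hits),
                w = IRanges::width(annotation$domain_index)[S4Vectors::subjectHits(hits)])
    h <- h |> arrange(.data$q, .data$w) |> distinct(.data$q, .keep_all = TRUE)
    out[h$q] <- names(annotation$domain_index)[h$s]
  }
  out
}

#' Classify the structural environment of a residue
#'
#' In explicit-table mode the bundled per-residue class is passed through
#' verbatim; otherwise, when a relative solvent accessibility (rsa) is
#' available, a residue is `buried` iff `rsa < rsa_threshold`. Positions with
#' neither an explicit class nor an rsa raise an error.
#'
#' @param position Integer vector of residue positions.
#' @param annotation A `protein_annotation` carrying an environment table.
#' @param rsa_threshold Buried/surface rsa cutoff (default 0.20).
#' @return Tibble with `position`, `location_class`, `between_helices`,
#'   `rsa`.
#' @export
classify_location <- function(position, annotation, rsa_threshold = 0.20) {
  stopifnot(inherits(annotation, "protein_annotation"))
  env <- annotation$environment
  if (is.null(env)) {
    abort("annotation has no per-residue environment table",
          class = "mutriage_error_annotation")
  }
  idx <- match(as.integer(position), env$position)
  if (anyNA(idx)) {
    abort(sprintf("no environment entry for position(s): %s",
                  paste(position[is.na(idx)], collapse = ", ")),
          class = "mutriage_error_missing_evidence")
  }
  cls <- env$location_class[idx]
  rsa <- env$rsa[idx]
  from_rsa <- is.na(cls) & !is.na(rsa)
  cls[from_rsa] <- ifelse(rsa[from_rsa] < rsa_threshold, "buried", "surface")
  if (anyNA(cls)) {
    abort(sprintf("position(s) lacking both explicit class and rsa: %s",
                  paste(position[is.na(cls)], collapse = ", ")),
          class = "mutriage_error_missing_evidence")
  }
  tibble(position = as.integer(position), location_class = cls,
         between_helices = as.integer(env$bh[idx] %in% 1L), rsa = rsa)
}

#' Sequence proximity of a residue to the binding-site registry
#'
#' Distance is the minimum absolute sequence separation between the position
#' and any registered site residue (0 inside a site interval);
#' `is_proximal` is `distance <= window`. An empty registry yields
#' `is_proximal = FALSE` with an infinite distance sentinel.
#'
#' @param position Integer vector of residue positions.
#' @param annotation A `protein_annotation`.
#' @param window Proximity window in residues (default 10).
#' @return Tibble with `position`, `is_proximal`, `nearest_site`,
#'   `distance`.
#' @export
binding_site_proximity <- function(position, annotation, window = 10L) {
  stopifnot(inherits(annotation, "protein_annotation"))
  position <- as.integer(position)
  n <- length(position)
  if (length(annotation$site_index) == 0) {
    return(tibble(position = position, is_proximal = rep(FALSE, n),
                  nearest_site = rep(NA_character_, n),
                  distance = rep(Inf, n)))
  }
  ## point-to-interval separation: 0 inside, else residues to the nearest end
  s <- IRanges::start(annotation$site_index)
  e <- IRanges::end(annotation$site_index)
  dmat <- vapply(seq_along(s), function(j) {
    pmax(s[j] - position, position - e[j], 0L)
  }, numeric(n))
  dmat <- matrix(dmat, nrow = n)
  nearest <- apply(dmat, 1, which.min)
  dist <- dmat[cbind(seq_len(n), nearest)]
  tibble(position = position,
         is_proximal = dist <= window,
         nearest_site = names(annotation$site_index)[nearest],
         distance = as.numeric(dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
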