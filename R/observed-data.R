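#' Construct an Experiment
#'
#' @param id experiment identifier.
#' @param segments data.frame with columns \code{segment}, \code{parent}
#'   (NA for the single root), optional \code{time}, and
#'   \code{substitutions}, a list column of compact substitution keys
#'   (e.g. \code{"A15T"}); a plain character vector of keys is accepted
#'   as shorthand for a single root segment.
#' @param temperatureClass "high" (>= 42 C), "normal" (<= 37 C) or
#'   "variable".
#' @param ancestorStart logical; adaptation started from the unmutated
#'   ancestor.
#' @param sourceLabel short letter code for the data source.
#' @return an [Experiment-class].
#' @examples
#' Experiment("exp1", c("A15T", "K92R"), temperatureClass = "high")
#' @export
Experiment <- function(id, segments, temperatureClass = "normal",
                       ancestorStart = TRUE, sourceLabel = "") {
  if (is.character(segments) || is.null(segments)) {
    keys <- as.character(segments)
    segments <- data.frame(segment = "root", parent = NA_character_,
                           time = NA_real_, stringsAsFactors = FALSE)
    segments$substitutions <- list(keys)
  }
  segs <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (!"time" %in% names(segs)) segs$time <- NA_real_
  if (!is.list(segs$substitutions))
    segs$substitutions <- as.list(segs$substitutions)
  rownames(segs) <- NULL
  new("Experiment", id = as.character(id),
      sourceLabel = as.character(sourceLabel),
      temperatureClass = temperatureClass,
      ancestorStart = isTRUE(ancestorStart),
      segments = segs[c("segment", "parent", "time", "substitutions")])
}

setMethod("show", "Experiment", function(object) {
  s <- object@segments
  cat("Experiment '", object@id, "' (", object@temperatureClass,
      " temperature", if (object@ancestorStart) ", ancestor start" else "",
      ")\n", sep = "")
  cat("  ", nrow(s), " segment(s), ",
      length(unique(unlist(s$substitutions))),
      " distinct substitution(s)\n", sep = "")
})

#' Substitutions implied by comparison with a consensus sequence
#'
#' Builds the column-wise consensus (most frequent residue) of aligned,
#' gap-free amino-acid sequences as a putative ancestral sequence, then
#' reports every (sequence, column) residue differing from the consensus
#' as a substitution consensus -> variant. Duplicates across sequences
#' collapse to unique keys.
#'
#' @param seqs character vector (or Biostrings AAStringSet) of >= 2
#'   aligned equal-length protein sequences.
#' @param tieBreak how to resolve consensus ties in a column:
#'   \code{"error"} (default) or \code{"first-in-alphabet"}.
#' @return data.frame with columns \code{site}, \code{aa_from}
#'   (consensus), \code{aa_to} (variant), ordered by site then target.
#' @export
consensusSubstitutions <- function(seqs,
                                   tieBreak = c("error",
                                                "first-in-alphabet")) {
  tieBreak <- match.arg(tieBreak)
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  checkAaLetters(as.vector(mat), "residue")
  L <- ncol(mat)
  out <- vector("list", L)
  for (s in seq_len(L)) {
    tab <- table(mat[, s])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      if (tieBreak == "error")
        stop("consensus tie at column ", s, " (",
             paste(top, collapse = "/"),
             "); supply tieBreak = \"first-in-alphabet\"")
      top <- sort(top)[1L]
    }
    var <- sort(setdiff(unique(mat[, s]), top))
    if (length(var))
      out[[s]] <- data.frame(site = s, aa_from = top, aa_to = var,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(site = integer(0), aa_from = character(0),
                      aa_to = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

## Look up ddG values for a vector of compact keys; errors naming any
## key absent from the table.
lookupDdg <- function(keys, table) {
  d <- ddgData(table)
  if (!length(keys))
    return(data.frame(ddg_fold = numeric(0), ddg_bind = numeric(0)))
  kd <- parseSubKey(keys)
  idx <- match(paste(kd$site, kd$aa_to), paste(d$site, d$aa_to))
  if (anyNA(idx))
    stop("substitution key(s) not in ddG table: ",
         paste(keys[is.na(idx)], collapse = ", "))
  from <- d$aa_from[idx]
  if (any(from != kd$aa_from))
    stop("aa_from mismatch with table for key(s): ",
         paste(keys[from != kd$aa_from], collapse = ", "))
  data.frame(ddg_fold = d$ddg_fold[idx], ddg_bind = d$ddg_bind[idx])
}

#' Cumulative stability trajectory of an experiment
#'
#' Walks the experiment's segment tree from the root (at ddG = (0, 0))
#' and accumulates, along each root-to-segment path, the summed ddG_fold
#' and ddG_bind of the substitutions fixed on every segment.
#'
#' @param exp an [Experiment-class].
#' @param table a [DdgTable-class] containing every referenced
#'   substitution.
#' @return data.frame with columns \code{segment}, \code{parent},
#'   \code{time}, \code{cum_ddg_fold}, \code{cum_ddg_bind}, one row per
#'   segment in parent-before-child order.
#' @export
cumulativeTrajectory <- function(exp, table) {
  stopifnot(is(exp, "Experiment"), is(table, "DdgTable"))
  s <- exp@segments
  segSum <- lapply(s$substitutions, function(keys) {
    v <- lookupDdg(keys, table)
    c(fold = sum(v$ddg_fold), bind = sum(v$ddg_bind))
  })
  cum <- stats::setNames(vector("list", nrow(s)), s$segment)
  ## parents precede children after a topological ordering
  ord <- integer(0)
  remaining <- seq_len(nrow(s))
  done <- character(0)
  while (length(remaining)) {
    ready <- remaining[is.na(s$parent[remaining]) |
                       s$parent[remaining] %in% done]
    if (!length(ready)) stop("segment graph is not a rooted tree")
    ord <- c(ord, ready)
    done <- c(done, s$segment[ready])
    remaining <- setdiff(remaining, ready)
  }
  for (i in ord) {
    base <- if (is.na(s$parent[i])) c(fold = 0, bind = 0)
            else cum[[s$parent[i]]]
    cum[[s$segment[i]]] <- base + segSum[[i]]
  }
  data.frame(segment = s$segment[ord], parent = s$parent[ord],
             time = s$time[ord],
             cum_ddg_fold = vapply(cum[s$segment[ord]], `[[`,
                                   numeric(1), "fold"),
             cum_ddg_bind = vapply(cum[s$segment[ord]], `[[`,
                                   numeric(1), "bind"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Radius enclosing all individual substitution effects
#'
#' The maximum Euclidean norm sqrt(ddg_fold^2 + ddg_bind^2) over a set of
#' substitutions: the radius of the circle within which every single
#' substitution falls, against which cumulative trajectories are judged.
#'
#' @param obs non-empty data.frame with \code{ddg_fold}, \code{ddg_bind}.
#' @return radius in kcal/mol.
#' @examples
#' individualEffectRadius(data.frame(ddg_fold = 3, ddg_bind = 4))  # 5
#' @export
individualEffectRadius <- function(obs) {
  if (is(obs, "DdgTable")) obs <- observedSubs(obs)
  if (!nrow(obs)) stop("empty substitution set")
  max(sqrt(obs$ddg_fold^2 + obs$ddg_bind^2))
}

#' Per-substitution experiment multiplicities
#'
#' Counts, for each substitution key, the number of distinct experiments
#' it appears in (a key occurring on several segments of one experiment
#' counts once), after optional filtering by temperature class and
#' ancestor start.
#'
#' @param experiments list of [Experiment-class] objects.
#' @param temperatureClass optional filter: "high", "normal" or
#'   "variable".
#' @param ancestorOnly logical; keep only experiments that started from
#'   the unmutated ancestor.
#' @return data.frame with columns \code{key}, \code{site},
#'   \code{aa_from}, \code{aa_to}, \code{weight}.
#' @export
experimentWeights <- function(experiments, temperatureClass = NULL,
                              ancestorOnly = FALSE) {
  keep <- vapply(experiments, function(e) {
    (is.null(temperatureClass) ||
       e@temperatureClass %in% temperatureClass) &&
      (!ancestorOnly || e@ancestorStart)
  }, logical(1))
  experiments <- experiments[keep]
  keys <- unlist(lapply(experiments, function(e)
    unique(unlist(e@segments$substitutions))))
  if (!length(keys))
    return(data.frame(key = character(0), site = integer(0),
                      aa_from = character(0), aa_to = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  tab <- table(keys)
  kd <- parseSubKey(names(tab))
  out <- data.frame(key = names(tab), site = kd$site,
                    aa_from = kd$aa_from, aa_to = kd$aa_to,
                    weight = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$site, out$aa_to), ]
  rownames(out) <- NULL
  out
}

#' Read and write experiment registries
#'
#' The registry is a YAML file with a top-level \code{experiments} list;
#' each entry has \code{id}, \code{source_label},
#' \code{temperature_class}, \code{ancestor_start} and a \code{segments}
#' list of records with \code{segment}, \code{parent} (omitted or null
#' for the root), optional \code{time}, and \code{substitutions}
#' (compact keys such as \code{"A15T"}).
#'
#' @param path registry file path.
#' @param experiments list of [Experiment-class] objects.
#' @return \code{readExperimentRegistry} returns a named list of
#'   [Experiment-class] objects.
#' @export
readExperimentRegistry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$experiments)) stop("registry has no 'experiments' list")
  exps <- lapply(doc$experiments, function(e) {
    segs <- do.call(rbind, lapply(e$segments, function(s) {
      data.frame(segment = s$segment,
                 parent = if (is.null(s$parent)) NA_character_ else
                   s$parent,
                 time = if (is.null(s$time)) NA_real_ else
                   as.numeric(s$time),
                 stringsAsFactors = FALSE)
    }))
    segs$substitutions <- lapply(e$segments, function(s)
      as.character(unlist(s$substitutions)))
    Experiment(id = e$id, segments = segs,
               temperatureClass = e$temperature_class,
               ancestorStart = isTRUE(e$ancestor_start),
               sourceLabel = if (is.null(e$source_label)) "" else
                 e$source_label)
  })
  stats::setNames(exps, vapply(exps, function(e) e@id, character(1)))
}

#' @rdname readExperimentRegistry
#' @export
writeExperimentRegistry <- function(experiments, path) {
  doc <- list(experiments = lapply(experiments, function(e) {
    s <- e@segments
    list(id = e@id, source_label = e@sourceLabel,
         temperature_class = e@temperatureClass,
         ancestor_start = e@ancestorStart,
         segments = lapply(seq_len(nrow(s)), function(i) {
           seg <- list(segment = s$segment[i])
           if (!is.na(s$parent[i])) seg$parent <- s$parent[i]
           if (!is.na(s$time[i])) seg$time <- s$time[i]
           seg$substitutions <- as.list(s$substitutions[[i]])
           seg
         }))
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write cumulative trajectories for a set of experiments
#'
#' @param experiments list of [Experiment-class] objects.
#' @param table a [DdgTable-class].
#' @param path output TSV path (experiment, segment, parent, time,
#'   cum_ddg_fold, cum_ddg_bind).
#' @export
writeTrajectories <- function(experiments, table, path) {
  rows <- lapply(experiments, function(e) {
    tr <- cumulativeTrajectory(e, table)
    cbind(experiment = e@id, tr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
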