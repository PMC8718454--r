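#' @keywords internal
"_PACKAGE"

# Severity labels, ordered from least to most severe. All labeling,
# confusion matrices and the integer coding (N=0 ... ES=4) use this order.
SEVERITY_LEVELS <- c("N", "M", "MD", "S", "ES")

SEVERITY_LONG <- c(
  N = "Normal", M = "Mild", MD = "Moderate", S = "Severe",
  ES = "Extremely Severe"
)

#' Severity labels used throughout the package
#'
#' Returns the five severity labels in increasing order of severity:
#' Normal (N), Mild (M), Moderate (MD), Severe (S), Extremely Severe (ES).
#'
#' @return Character vector of length 5.
#' @export
severity_levels <- function() SEVERITY_LEVELS

#' Construct a disorder query set
#'
#' A disorder set names one of the three DASS-42 subscales, lists its 14
#' query columns, and carries the Weight-Score band table used for severity
#' labeling plus the default relevance threshold used by Q-Prioritization.
#'
#' @param name One of `"anxiety"`, `"stress"`, `"depression"`.
#' @param queries Character vector of 14 query ids (e.g. `"Q2"`).
#' @param bands Data frame with columns `label`, `lo`, `hi` giving the
#'   inclusive Weight-Score interval of each severity band. Bands may
#'   overlap at a boundary; [assign_severity()] resolves overlaps by
#'   giving the more severe band precedence.
#' @param rth Default relevance threshold for this set.
#' @return An object of class `disorder_set`.
#' @seealso [default_disorder_sets()]
#' @export
disorder_set <- function(name, queries, bands, rth) {
  stopifnot(is.character(queries), length(queries) == 14L,
            !anyDuplicated(queries))
  stopifnot(is.data.frame(bands),
            all(c("label", "lo", "hi") %in% names(bands)))
  if (!setequal(bands$label, SEVERITY_LEVELS))
    stop("bands must define exactly the five severity levels N/M/MD/S/ES")
  bands <- bands[match(SEVERITY_LEVELS, bands$label), , drop = FALSE]
  covered <- unlist(Map(seq.int, bands$lo, bands$hi))
  if (!all(0:42 %in% covered))
    stop("bands must cover every integer Weight Score in [0, 42]")
  normal_max <- bands$hi[bands$label == "N"]
  structure(
    list(name = name, queries = queries, bands = bands,
         normal_max = as.integer(normal_max), rth = rth),
    class = "disorder_set"
  )
}

#' @export
print.disorder_set <- function(x, ...) {
  cat(sprintf("<disorder_set> %s: %d queries (%s ...)\n", x$name,
              length(x$queries), paste(x$queries[1:4], collapse = ", ")))
  cat(sprintf("  normal_max = %d, default Rth = %g\n", x$normal_max, x$rth))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

make_bands <- function(n_hi, m, md, s, es_lo) {
  data.frame(
    label = SEVERITY_LEVELS,
    lo = c(0L, m[1], md[1], s[1], es_lo),
    hi = c(n_hi, m[2], md[2], s[2], 42L)
  )
}

#' The three DASS-42 disorder query sets
#'
#' The 42 DASS queries partition into three 14-item subscales. Each set
#' carries its published Weight-Score severity bands (Extremely Severe
#' starting at WS 20/33/28 for anxiety/stress/depression, Severe at
#' 15-19/26-33/21-27, Moderate at 10-14/19-25/14-20, Mild at 8-9/15-18/
#' 10-13, anything below Normal) and its default relevance threshold
#' (0.5/1.0/0.2). The stress Severe and Extremely Severe bands share the
#' boundary value 33; severity assignment resolves it in favour of the
#' more severe label.
#'
#' @return Named list of three [disorder_set] objects
#'   (`anxiety`, `stress`, `depression`).
#' @examples
#' sets <- default_disorder_sets()
#' sets$anxiety$queries
#' @export
default_disorder_sets <- function() {
  list(
    anxiety = disorder_set(
      "anxiety",
      c("Q2", "Q4", "Q7", "Q9", "Q15", "Q19", "Q20", "Q23", "Q25", "Q28",
        "Q30", "Q36", "Q40", "Q41"),
      make_bands(7L, c(8L, 9L), c(10L, 14L), c(15L, 19L), 20L),
      rth = 0.5
    ),
    stress = disorder_set(
      "stress",
      c("Q1", "Q6", "Q8", "Q11", "Q12", "Q14", "Q18", "Q22", "Q27", "Q29",
        "Q32", "Q33", "Q35", "Q39"),
      make_bands(14L, c(15L, 18L), c(19L, 25L), c(26L, 33L), 33L),
      rth = 1.0
    ),
    depression = disorder_set(
      "depression",
      c("Q3", "Q5", "Q10", "Q13", "Q16", "Q17", "Q21", "Q24", "Q26", "Q31",
        "Q34", "Q37", "Q38", "Q42"),
      make_bands(9L, c(10L, 13L), c(14L, 20L), c(21L, 27L), 28L),
      rth = 0.2
    )
  )
}

#' Load disorder sets with custom severity bands from a YAML file
#'
#' The YAML file maps disorder names to a list with `queries` (14 ids),
#' `bands` (label -> `[lo, hi]`) and optionally `rth`. Disorders absent
#' from the file keep their defaults, so a file can override just one
#' band table (e.g. to swap in revised cutoffs).
#'
#' @param path Path to a YAML band configuration.
#' @return Named list of [disorder_set] objects.
#' @export
load_disorder_sets <- function(path) {
  cfg <- yaml::read_yaml(path)
  sets <- default_disorder_sets()
  for (nm in names(cfg)) {
    if (!nm %in% names(sets))
      stop("unknown disorder in band config: ", nm)
    spec <- cfg[[nm]]
    queries <- if (!is.null(spec$queries)) as.character(spec$queries)
               else sets[[nm]]$queries
    bands <- if (!is.null(spec$bands)) {
      b <- spec$bands
      # YAML 1.1 reads a bare N key as boolean; map it back
      names(b)[names(b) == "FALSE"] <- "N"
      data.frame(label = names(b),
                 lo = vapply(b, function(v) as.integer(v[[1]]), 0L),
                 hi = vapply(b, function(v) as.integer(v[[2]]), 0L))
    } else sets[[nm]]$bands
    rth <- if (!is.null(spec$rth)) as.numeric(spec$rth) else sets[[nm]]$rth
    sets[[nm]] <- disorder_set(nm, queries, bands, rth)
  }
  sets
}
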