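#' Default tissue classes
#'
#' The 12 tissue types segmented by the upstream network, plus background.
#' Codes are the integer pixel values of the label raster.
#'
#' @return data.frame with columns `code` and `name`.
#' @export
default_tissue_classes <- function() {
  data.frame(
    code = 0:12,
    name = c("background", "tumor glands", "tumor-associated stroma",
             "necrosis", "lymphocytes", "erythrocytes", "muscle",
             "healthy stroma", "fatty tissue", "mucus", "nerve",
             "stroma lamina propria", "healthy glands"),
    stringsAsFactors = FALSE
  )
}

# Role groupings, by class name. Two stroma definitions coexist on purpose:
# the semi-automated score counts muscle, healthy stroma and stroma lamina
# propria as stromal, while the fully automated score restricts stroma to
# tumor-associated stroma, lymphocytes, nerve and erythrocytes, and pairs it
# with a tumor set of tumor glands + healthy glands (healthy glands inside
# the bulk behave as well-differentiated tumor glands).
default_groupings <- function() {
  list(
    tumor_full   = c("tumor glands", "healthy glands"),
    stroma_full  = c("tumor-associated stroma", "lymphocytes", "nerve",
                     "erythrocytes"),
    stroma_semi  = c("tumor-associated stroma", "lymphocytes",
                     "erythrocytes", "muscle", "healthy stroma", "nerve",
                     "stroma lamina propria"),
    denominator_excluded_semi = c("mucus", "necrosis", "background"),
    fat          = "fatty tissue",
    erythrocytes = "erythrocytes",
    necrosis     = "necrosis"
  )
}

#' Tissue class scheme
#'
#' Binds integer raster codes to tissue-class names and to the role
#' groupings used by the scoring formulas (tumor set, the two stroma sets,
#' semi-mode denominator exclusions, and the nuisance classes checked by the
#' field-of-view validity rules). Groupings may be overridden; any grouping
#' not supplied is filled from the defaults, restricted to classes actually
#' present in `entries`.
#'
#' @param entries data.frame with columns `code` (unique non-negative
#'   integers) and `name`; defaults to [default_tissue_classes()].
#' @param groupings named list mapping grouping names to character vectors
#'   of class names (or integer code vectors).
#' @return object of class `tissue_scheme`: list with `entries` and
#'   `groupings` (the latter resolved to integer code vectors).
#' @export
tissue_scheme <- function(entries = default_tissue_classes(),
                          groupings = NULL) {
  entries <- as.data.frame(entries)
  if (!all(c("code", "name") %in% names(entries)))
    tsr_stop("tsr_format_error", "scheme entries need 'code' and 'name' columns")
  entries$code <- as.integer(entries$code)
  if (anyNA(entries$code) || any(entries$code < 0))
    tsr_stop("tsr_format_error", "class codes must be non-negative integers")
  if (anyDuplicated(entries$code))
    tsr_stop("tsr_format_error", sprintf(
      "duplicate class code: %d", entries$code[duplicated(entries$code)][1]))
  if (anyDuplicated(entries$name))
    tsr_stop("tsr_format_error", "duplicate class name in scheme")
  if (!"background" %in% entries$name)
    tsr_stop("tsr_format_error", "scheme must declare a 'background' class")

  resolve <- function(g) {
    if (is.numeric(g)) {
      g <- as.integer(g)
      if (!all(g %in% entries$code))
        tsr_stop("tsr_format_error", sprintf(
          "grouping references unknown code: %d", setdiff(g, entries$code)[1]))
      return(sort(g))
    }
    unknown <- setdiff(g, entries$name)
    if (length(unknown))
      tsr_stop("tsr_format_error", sprintf(
        "grouping references unknown class: '%s'", unknown[1]))
    sort(entries$code[match(g, entries$name)])
  }

  def <- default_groupings()
  res <- list()
  for (nm in union(names(def), names(groupings))) {
    if (!is.null(groupings[[nm]])) {
      res[[nm]] <- resolve(groupings[[nm]])
    } else {
      # default grouping, silently restricted to declared classes
      res[[nm]] <- resolve(intersect(def[[nm]], entries$name))
    }
  }
  if (length(intersect(res$tumor_full, res$stroma_full)))
    tsr_stop("tsr_format_error", "'tumor_full' and 'stroma_full' must be disjoint")

  structure(list(entries = entries, groupings = res),
            class = "tissue_scheme")
}

#' Codes belonging to a grouping
#'
#' @param scheme a [tissue_scheme()].
#' @param group grouping name, e.g. `"stroma_full"`.
#' @return integer vector of class codes.
#' @export
scheme_codes <- function(scheme, group) {
  g <- scheme$groupings[[group]]
  if (is.null(g))
    tsr_stop("tsr_input_error", sprintf("unknown grouping '%s'", group))
  g
}

# code of the background class
background_code <- function(scheme) {
  scheme$entries$code[scheme$entries$name == "background"]
}

#' Read a tissue-class scheme from a YAML config
#'
#' The config declares `classes:` as a code-to-name map and optionally
#' `groupings:` as name-to-class-name lists; missing groupings are filled
#' from the package defaults.
#'
#' @param path path to a YAML file.
#' @return a [tissue_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path))
    tsr_stop("tsr_format_error", sprintf("scheme file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$classes))
    tsr_stop("tsr_format_error", "scheme config must have a 'classes' block")
  codes <- suppressWarnings(as.integer(names(cfg$classes)))
  if (anyNA(codes))
    tsr_stop("tsr_format_error", "class codes in config must be integers")
  entries <- data.frame(code = codes,
                        name = unname(unlist(cfg$classes)),
                        stringsAsFactors = FALSE)
  tissue_scheme(entries, groupings = cfg$groupings)
}

#' Write a tissue-class scheme to a YAML config
#'
#' @param scheme a [tissue_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  classes <- as.list(scheme$entries$name)
  names(classes) <- as.character(scheme$entries$code)
  groupings <- lapply(scheme$groupings, function(codes) {
    as.list(scheme$entries$name[match(codes, scheme$entries$code)])
  })
  yaml::write_yaml(list(classes = classes, groupings = groupings), path)
  invisible(path)
}

#' @export
print.tissue_scheme <- function(x, ...) {
  cat(sprintf("Tissue class scheme: %d classes\n", nrow(x$entries)))
  cat(paste(sprintf("  %2d %s", x$entries$code, x$entries$name),
            collapse = "\n"), "\n")
  cat("Groupings:\n")
  for (nm in names(x$groupings))
    cat(sprintf("  %-26s {%s}\n", nm,
                paste(x$groupings[[nm]], collapse = ",")))
  invisible(x)
}
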