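# cdm_model: declarative CDM schema -- loading, validation of the schema
# itself, serialization, and structural validation of a DataMart refresh
# against it. The schema is entirely config-driven (YAML/JSON): tables,
# fields, kinds, value sets, keys and the per-table date field used for
# temporal windowing.

FIELD_KINDS <- c("text", "coded", "date", "datetime", "numeric", "identifier")

#' Load a CDM schema from a configuration document
#'
#' Reads a YAML (or JSON) schema document declaring tables, fields, value
#' sets and key relationships, validates its internal consistency, and
#' returns a `cdm_schema` object. The packaged default (used when `source`
#' is omitted) is a reduced 8-table core of a PCORnet-style CDM:
#' DEMOGRAPHIC, ENCOUNTER, DIAGNOSIS, PROCEDURES, PRESCRIBING,
#' LAB_RESULT_CM, VITAL and DEATH.
#'
#' @param source path to a schema YAML/JSON file, or an already-parsed list.
#'   Defaults to the packaged 8-table core schema.
#' @return an object of class `cdm_schema`: a list with `version_label`,
#'   `value_sets` (named list of code vectors), `tables` (named list of
#'   table specs) and `required_tables`.
#' @export
#' @examples
#' schema <- load_schema()
#' names(schema$tables)
load_schema <- function(source = NULL) {
  if (is.null(source)) source <- cdm_resource("cdm_schema.yaml")
  doc <- if (is.character(source)) yaml::read_yaml(source) else source
  if (!is.list(doc) || is.null(doc$tables) || length(doc$tables) == 0) {
    stopf("schema parse error: document declares no tables")
  }

  value_sets <- lapply(doc$value_sets %||% list(), function(vs) {
    codes <- as.character(vs$codes %||% vs)
    if (length(codes) == 0) stopf("schema parse error: empty value set")
    if (anyDuplicated(codes)) stopf("schema parse error: duplicate codes in a value set")
    list(codes = codes, description = vs$description %||% "")
  })

  tables <- list()
  for (tname in names(doc$tables)) {
    tdoc <- doc$tables[[tname]]
    if (is.null(tdoc$fields) || length(tdoc$fields) == 0) {
      stopf("schema parse error: table %s declares no fields", tname)
    }
    fields <- lapply(tdoc$fields, function(f) {
      if (is.null(f$name) || is.null(f$kind)) {
        stopf("schema parse error: table %s has a field without name/kind", tname)
      }
      if (!f$kind %in% FIELD_KINDS) {
        stopf("schema parse error: field %s.%s has unknown kind '%s'",
              tname, f$name, f$kind)
      }
      if (f$kind == "coded") {
        if (is.null(f$value_set)) {
          stopf("schema parse error: coded field %s.%s lacks a value_set", tname, f$name)
        }
        if (!f$value_set %in% names(value_sets)) {
          stopf("schema consistency error: field %s.%s references unknown value set %s",
                tname, f$name, f$value_set)
        }
      }
      list(name = f$name, kind = f$kind, value_set = f$value_set %||% NA_character_,
           required = isTRUE(f$required), nullable = !isFALSE(f$nullable),
           ref_table = f$references$table %||% NA_character_,
           ref_field = f$references$field %||% NA_character_)
    })
    fnames <- vapply(fields, `[[`, "", "name")
    if (anyDuplicated(fnames)) {
      stopf("schema parse error: duplicate field names in table %s", tname)
    }
    pk <- tdoc$primary_key
    if (is.null(pk) || !pk %in% fnames) {
      stopf("schema consistency error: table %s primary_key does not name a field", tname)
    }
    tables[[tname]] <- list(name = tname, primary_key = pk,
                            date_field = tdoc$date_field %||% NA_character_,
                            fields = fields)
    if (!is.na(tables[[tname]]$date_field) &&
        !tables[[tname]]$date_field %in% fnames) {
      stopf("schema consistency error: table %s date_field %s is not a field",
            tname, tables[[tname]]$date_field)
    }
  }

  # foreign keys must land on an existing (table, field) pair
  for (tname in names(tables)) {
    for (f in tables[[tname]]$fields) {
      if (!is.na(f$ref_table)) {
        tgt <- tables[[f$ref_table]]
        if (is.null(tgt)) {
          stopf("schema consistency error: %s.%s references absent table %s",
                tname, f$name, f$ref_table)
        }
        if (!f$ref_field %in% vapply(tgt$fields, `[[`, "", "name")) {
          stopf("schema consistency error: %s.%s references absent field %s.%s",
                tname, f$name, f$ref_table, f$ref_field)
        }
      }
    }
  }

  required_tables <- as.character(doc$required_tables %||% names(tables)[1])
  if (!all(required_tables %in% names(tables))) {
    stopf("schema consistency error: required_tables lists unknown tables: %s",
          paste(setdiff(required_tables, names(tables)), collapse = ", "))
  }

  structure(list(version_label = doc$version %||% "unversioned",
                 value_sets = value_sets, tables = tables,
                 required_tables = required_tables),
            class = "cdm_schema")
}

#' @export
print.cdm_schema <- function(x, ...) {
  cat("<cdm_schema>", x$version_label, "\n")
  cat(" tables:", paste(names(x$tables), collapse = ", "), "\n")
  cat(" required:", paste(x$required_tables, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a CDM schema back to a configuration document
#'
#' Writes a YAML document that [load_schema()] reads back into an identical
#' schema (serialization round-trip stability).
#'
#' @param schema a `cdm_schema`.
#' @param path output file path; when `NULL` the document list is returned.
#' @return invisibly, the path (or the document list when `path = NULL`).
#' @export
render_schema <- function(schema, path = NULL) {
  doc <- list(
    version = schema$version_label,
    required_tables = as.list(schema$required_tables),
    value_sets = lapply(schema$value_sets, function(vs) {
      list(description = vs$description, codes = as.list(vs$codes))
    }),
    tables = lapply(schema$tables, function(tb) {
      list(primary_key = tb$primary_key,
           date_field = if (is.na(tb$date_field)) NULL else tb$date_field,
           fields = lapply(tb$fields, function(f) {
             out <- list(name = f$name, kind = f$kind,
                         required = f$required, nullable = f$nullable)
             if (!is.na(f$value_set)) out$value_set <- f$value_set
             if (!is.na(f$ref_table)) {
               out$references <- list(table = f$ref_table, field = f$ref_field)
             }
             out
           }))
    })
  )
  if (is.null(path)) return(invisible(doc))
  yaml::write_yaml(doc, path)
  invisible(path)
}

schema_field <- function(schema, table, field) {
  tb <- schema$tables[[table]]
  if (is.null(tb)) return(NULL)
  for (f in tb$fields) if (f$name == field) return(f)
  NULL
}

schema_field_names <- function(schema, table) {
  vapply(schema$tables[[table]]$fields, `[[`, "", "name")
}

# Fields of a given kind across the schema: data.frame(table, field).
schema_fields_of_kind <- function(schema, kinds) {
  rows <- list()
  for (tb in schema$tables) {
    for (f in tb$fields) {
      if (f$kind %in% kinds) {
        rows[[length(rows) + 1L]] <- data.frame(table = tb$name, field = f$name,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  rbind_all(rows) %||% data.frame(table = character(0), field = character(0))
}

structural_finding <- function(kind, table, field = NA_character_, n = 1L,
                               detail = "") {
  data.frame(kind = kind, table = table, field = field, n = as.integer(n),
             detail = detail, stringsAsFactors = FALSE)
}

#' Validate the structure of a refresh against a schema
#'
#' Produces one finding per missing required table, per missing required
#' field, and per value that fails to parse as its declared kind (date,
#' datetime or numeric). An empty finding set means the refresh is fully
#' structurally conformant. Findings are what the conformance checks of the
#' packaged catalog consume.
#'
#' @param refresh a `datamart_refresh` (see [read_refresh()] /
#'   [generate_datamart()]).
#' @param schema a `cdm_schema`.
#' @return a data frame with columns `kind` (one of
#'   `missing-required-table`, `missing-required-field`,
#'   `unparseable-value`), `table`, `field`, `n` and `detail`; zero rows iff
#'   conformant.
#' @export
validate_structure <- function(refresh, schema) {
  findings <- list()
  for (tname in schema$required_tables) {
    if (is.null(refresh$tables[[tname]])) {
      findings[[length(findings) + 1L]] <-
        structural_finding("missing-required-table", tname)
    }
  }
  for (tname in names(schema$tables)) {
    tab <- refresh$tables[[tname]]
    if (is.null(tab)) next
    for (f in schema$tables[[tname]]$fields) {
      if (f$required && !f$name %in% names(tab)) {
        findings[[length(findings) + 1L]] <-
          structural_finding("missing-required-field", tname, f$name)
      }
    }
  }
  # unparseable values are recorded at load time (read_refresh); expand one
  # finding per offending value
  pe <- refresh$parse_errors
  if (!is.null(pe) && nrow(pe) > 0) {
    for (i in seq_len(nrow(pe))) {
      findings[[length(findings) + 1L]] <- structural_finding(
        "unparseable-value", pe$table[i], pe$field[i], n = 1L,
        detail = pe$value[i])
    }
  }
  rbind_all(findings) %||%
    structural_finding("none", "none")[0, ]
}
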