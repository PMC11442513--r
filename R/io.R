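#' Construct a multichannel LFP recording
#'
#' A recording holds monopolar (or pre-bipolarized) samples for one
#' hemisphere of one subject, together with the contact labels in
#' anatomical order (ventral to dorsal) and the mapping from contact to
#' basal ganglia structure. Contact adjacency in `contacts` defines the
#' bipolar montage used by [derive_bipolar()].
#'
#' @param subject_id subject identifier (scalar).
#' @param hemisphere `"left"` or `"right"`.
#' @param fs sampling frequency in Hz.
#' @param samples numeric matrix, contacts x time.
#' @param contacts character vector of contact labels, ventral to dorsal;
#'   defaults to `"c1"..."cN"`.
#' @param contact_structure named character vector mapping every contact to
#'   one of `"STR"`, `"GPe"`, `"GPi"` or `"other"`.
#' @param bipolar logical; `TRUE` when the rows of `samples` are already
#'   bipolar derivations rather than monopolar contacts.
#' @return an object of class `bg_recording`.
#' @export
new_recording <- function(subject_id, hemisphere, fs, samples,
                          contacts = NULL, contact_structure = NULL,
                          bipolar = FALSE) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  n_contacts <- nrow(samples)
  if (is.null(contacts)) contacts <- paste0("c", seq_len(n_contacts))
  if (length(contacts) != n_contacts) {
    stopf("contact labels (%d) do not match sample rows (%d)",
          length(contacts), n_contacts)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stopf("fs must be a positive scalar (got %s)", deparse(fs))
  }
  if (!hemisphere %in% c("left", "right")) {
    stopf("hemisphere must be 'left' or 'right' (got '%s')", hemisphere)
  }
  if (is.null(contact_structure)) {
    contact_structure <- setNames(rep("other", n_contacts), contacts)
  }
  if (!all(contacts %in% names(contact_structure))) {
    stopf("contact_structure is missing contacts: %s",
          paste(setdiff(contacts, names(contact_structure)), collapse = ", "))
  }
  contact_structure <- contact_structure[contacts]
  unknown <- !contact_structure %in% c(BG_STRUCTURES, "other")
  contact_structure[unknown] <- "other"
  rownames(samples) <- contacts
  structure(
    list(subject_id = subject_id, hemisphere = hemisphere, fs = fs,
         contacts = contacts, samples = samples,
         contact_structure = contact_structure, bipolar = isTRUE(bipolar)),
    class = "bg_recording"
  )
}

#' @export
print.bg_recording <- function(x, ...) {
  cat(sprintf("<bg_recording> subject %s, %s hemisphere\n",
              x$subject_id, x$hemisphere))
  cat(sprintf("  %d contacts x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs,
              if (x$bipolar) ", pre-bipolarized" else ""))
  cat("  structures:",
      paste(sprintf("%s=%s", x$contacts, x$contact_structure),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a recording to disk
#'
#' The native on-disk format is raw little-endian float64 samples in
#' channel-major order plus a JSON sidecar holding `fs`, contact labels,
#' the contact-to-structure map and identity fields. A delimited-text (TSV)
#' format with the same sidecar is available for portability.
#'
#' @param rec a [new_recording()] object.
#' @param path sample file path (`.bin` or `.tsv`).
#' @param metadata_path sidecar path; defaults to `path` with `.json`
#'   appended.
#' @param format `"binary"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, metadata_path = NULL,
                            format = c("binary", "tsv")) {
  format <- match.arg(format)
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  meta <- list(
    subject_id = rec$subject_id, hemisphere = rec$hemisphere,
    fs = rec$fs, contacts = rec$contacts,
    contact_structure = as.list(rec$contact_structure),
    n_samples = ncol(rec$samples), bipolar = rec$bipolar,
    format = format
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    # channel-major: all samples of contact 1, then contact 2, ...
    writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
  } else {
    m <- t(rec$samples)
    colnames(m) <- rec$contacts
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads the native binary or TSV format written by [write_recording()],
#' validating the sidecar metadata against the sample payload.
#'
#' @param path sample file path.
#' @param metadata_path JSON sidecar path; defaults to `path` + `.json`.
#' @return a `bg_recording`.
#' @export
read_recording <- function(path, metadata_path = NULL) {
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  if (!file.exists(path)) stopf("sample file not found: %s", path)
  if (!file.exists(metadata_path)) {
    stopf("metadata sidecar not found: %s", metadata_path)
  }
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (field in c("fs", "contacts", "n_samples")) {
    if (is.null(meta[[field]])) {
      stopf("metadata %s is missing required field '%s'",
            metadata_path, field)
    }
  }
  n_contacts <- length(meta$contacts)
  n_samples <- as.integer(meta$n_samples)
  if (identical(meta$format, "tsv") || grepl("\\.tsv$", path)) {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
    if (ncol(m) != n_contacts) {
      stopf("sample file has %d channels but metadata lists %d contacts",
            ncol(m), n_contacts)
    }
    samples <- t(m)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n_contacts * n_samples + 1,
                    size = 8, endian = "little")
    if (length(vals) != n_contacts * n_samples) {
      stopf("sample file holds %d values; metadata implies %d (%d contacts x %d samples)",
            length(vals), n_contacts * n_samples, n_contacts, n_samples)
    }
    samples <- matrix(vals, nrow = n_contacts, byrow = TRUE)
  }
  if (ncol(samples) != n_samples) {
    stopf("sample count %d does not match metadata n_samples %d",
          ncol(samples), n_samples)
  }
  cs <- unlist(meta$contact_structure)
  new_recording(meta$subject_id %||% "unknown",
                meta$hemisphere %||% "left",
                fs = meta$fs, samples = samples,
                contacts = meta$contacts,
                contact_structure = cs,
                bipolar = isTRUE(meta$bipolar))
}

#' Derive the bipolar montage from adjacent contacts
#'
#' Eight monopolar contacts yield seven parallel bipolar channels per
#' hemisphere. The sign convention is ventral minus dorsal contact; a
#' bipolar channel is assigned to a structure only when both member
#' contacts are localized in that same structure.
#'
#' @param rec a `bg_recording` with monopolar contacts.
#' @return list of `bg_bipolar` channels in ventral-to-dorsal order, each
#'   with fields `pair` (contact indices), `labels`, `samples`, and
#'   `structure` (`NA` when the pair straddles structures).
#' @export
derive_bipolar <- function(rec) {
  stopifnot(inherits(rec, "bg_recording"))
  if (rec$bipolar) {
    stopf("recording is already bipolarized; derive_bipolar expects monopolar contacts")
  }
  n <- nrow(rec$samples)
  if (n < 2) stopf("need at least 2 contacts to derive a bipolar montage (got %d)", n)
  lapply(seq_len(n - 1), function(i) {
    s_i <- rec$contact_structure[i]
    s_j <- rec$contact_structure[i + 1]
    str <- if (s_i == s_j && s_i %in% BG_STRUCTURES) s_i else NA_character_
    structure(
      list(pair = c(i, i + 1),
           labels = rec$contacts[c(i, i + 1)],
           samples = rec$samples[i, ] - rec$samples[i + 1, ],
           structure = str,
           fs = rec$fs),
      class = "bg_bipolar"
    )
  })
}

#' Retain one structure-assigned bipolar channel per structure
#'
#' Keeps exactly the bipolar channels whose two contacts are localized in
#' the same structure and discards all mixed pairs. When several adjacent
#' pairs lie fully inside the same structure, the most ventral pair is
#' retained (documented tie-break).
#'
#' @param channels list of `bg_bipolar` from [derive_bipolar()].
#' @param mapping optional contact-to-structure map overriding the one the
#'   channels were derived with (named character vector, indexed by contact
#'   label).
#' @return named list keyed by structure (`"STR"`, `"GPe"`, `"GPi"`);
#'   structures with no fully-contained pair are absent. Emits a warning
#'   and returns an empty list when nothing is retained.
#' @export
assign_structures <- function(channels, mapping = NULL) {
  stopifnot(length(channels) >= 1)
  get_struct <- function(ch) {
    if (is.null(mapping)) return(ch$structure)
    if (!all(ch$labels %in% names(mapping))) {
      stopf("mapping does not cover contacts: %s",
            paste(setdiff(ch$labels, names(mapping)), collapse = ", "))
    }
    s <- unname(mapping[ch$labels])
    if (s[1] == s[2] && s[1] %in% BG_STRUCTURES) s[1] else NA_character_
  }
  out <- list()
  for (ch in channels) {
    s <- get_struct(ch)
    if (is.na(s)) next
    if (is.null(out[[s]])) {
      ch$structure <- s
      out[[s]] <- ch   # channels arrive ventral-first, so first wins
    }
  }
  if (length(out) == 0) {
    warnf("no bipolar pair is fully contained in any structure; returning empty set")
  }
  out[intersect(BG_STRUCTURES, names(out))]
}
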