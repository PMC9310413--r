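# Internal condition constructors and small coding helpers.

sgcError <- function(class, msg, ...) {
  stop(structure(class = c(class, "sgc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

sgcParseError      <- function(msg, ...) sgcError("sgc_parse_error", msg, ...)
sgcCorruptionError <- function(msg, ...) sgcError("sgc_corruption_error", msg, ...)
sgcUsageError      <- function(msg, ...) sgcError("sgc_usage_error", msg, ...)
sgcFormatError     <- function(msg, ...) sgcError("sgc_format_error", msg, ...)
sgcConfigError     <- function(msg, ...) sgcError("sgc_config_error", msg, ...)
sgcIOError         <- function(msg, ...) sgcError("sgc_io_error", msg, ...)
sgcWrongReferenceError <- function(msg, ...) sgcError("sgc_wrong_reference_error", msg, ...)

#' Variable-length integer coding
#'
#' Encode non-negative integers in the standard 7-bit-continuation varint
#' form, optionally zigzag-mapping signed values first, and decode them back.
#' These are the primitives behind every integer field of the archive format.
#'
#' @param x numeric vector of integral values (negative values require
#'   \code{zigzag = TRUE}).
#' @param zigzag map signed values through the zigzag interleaving
#'   \eqn{(n << 1) XOR (n >> 63)} before/after the byte coding.
#' @return \code{encodeVarint}: a raw vector. \code{decodeVarint}: a numeric
#'   vector of \code{n} decoded values.
#' @examples
#' encodeVarint(0)            # one byte 00
#' length(encodeVarint(300))  # two bytes
#' decodeVarint(encodeVarint(c(-5, 7), zigzag = TRUE), 2, zigzag = TRUE)
#' @export
encodeVarint <- function(x, zigzag = FALSE) {
  cpp_encode_varints(as.numeric(x), isTRUE(zigzag))
}

#' @rdname encodeVarint
#' @param bytes raw vector holding varints.
#' @param n number of values to decode.
#' @param offset 0-based byte offset at which decoding starts.
#' @export
decodeVarint <- function(bytes, n, zigzag = FALSE, offset = 0) {
  tryCatch(cpp_decode_varints(bytes, offset, as.integer(n), isTRUE(zigzag))$values,
           error = function(e) sgcCorruptionError(conditionMessage(e)))
}

# streaming decode used by the archive/aux readers: returns values + new offset
readVarints <- function(bytes, offset, n, zigzag = FALSE) {
  tryCatch(cpp_decode_varints(bytes, offset, as.integer(n), isTRUE(zigzag)),
           error = function(e) sgcCorruptionError(conditionMessage(e)))
}

# 64-bit FNV-1a content fingerprint of a raw vector or character scalar
fingerprintBytes <- function(x) {
  if (is.character(x)) x <- charToRaw(x)
  cpp_fnv64(x)
}
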