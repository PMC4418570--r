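# internal helpers

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, lo = -Inf, hi = Inf, allow_vec = FALSE) {
  if (!is.numeric(x) || (!allow_vec && length(x) != 1L) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric %s", name,
                 if (allow_vec) "vector" else "scalar"), call. = FALSE)
  }
  if (any(x < lo) || any(x > hi)) {
    stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

# deep-merge override list into defaults, rejecting keys absent from defaults
merge_config <- function(defaults, overrides, path = "") {
  if (length(overrides) == 0L) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop("configuration overrides must be a named list at ", path, call. = FALSE)
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in nm) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(overrides[[k]]),
                                    path = paste0(path, k, "."))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

JOULES_PER_KCAL <- 4184
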