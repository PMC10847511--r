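# Row-bind a list of data.frames without row-name mangling; NULL when the
# list is empty (callers supply their own empty-table fallback).
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}
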