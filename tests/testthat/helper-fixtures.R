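# Shared fixtures built in code. The default design/template are cached so
# repeated tests do not rebuild them.

default_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- library_design()
    d
  }
})

default_template <- function() default_design()$template

# a clone sequence with given CDR3 realizations embedded in the template
make_clone <- function(vl_nt = NULL, vh_nt = NULL, template = default_template()) {
  vl_iv <- template$intervals[template$intervals$region == "VL", ]
  vh_iv <- template$intervals[template$intervals$region == "VH", ]
  s <- template$sequence
  if (is.null(vl_nt)) vl_nt <- substr(s, vl_iv$start + 1L, vl_iv$end)
  if (is.null(vh_nt)) vh_nt <- substr(s, vh_iv$start + 1L, vh_iv$end)
  paste0(substr(s, 1L, vl_iv$start), vl_nt,
         substr(s, vl_iv$end + 1L, vh_iv$start), vh_nt,
         substr(s, vh_iv$end + 1L, nchar(s)))
}

# flip one base at 1-based position pos
flip_base <- function(seq, pos) {
  b <- substr(seq, pos, pos)
  sub <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
  paste0(substr(seq, 1L, pos - 1L), sub, substr(seq, pos + 1L, nchar(seq)))
}

# arm of given length with an exact number of G/C bases
arm_with_gc <- function(n_gc, len)
  paste0(strrep("G", n_gc), strrep("A", len - n_gc))
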