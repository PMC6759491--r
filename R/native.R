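# Thin .Call wrappers over the big-integer limb kernels in src/bignum.cpp.

.bn_addmul <- function(a, b, m) {
  .Call("_dhcross_bn_addmul", as.numeric(a), as.numeric(b), as.numeric(m),
        PACKAGE = "dhcross")
}

.bn_mul <- function(a, b) {
  .Call("_dhcross_bn_mul", as.numeric(a), as.numeric(b), PACKAGE = "dhcross")
}

.bn_cmp <- function(a, b) {
  .Call("_dhcross_bn_cmp", as.numeric(a), as.numeric(b), PACKAGE = "dhcross")
}
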