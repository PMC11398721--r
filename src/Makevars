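# Build with the system toolchain.  The conda cross-compiler targets a
# newer glibc than the host runtime provides, so its objects fail to
# load ("version GLIBC_2.38 not found").  R includes this file before
# Makeconf, hence the override directives.
override CC = gcc
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override CXX20 = g++
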