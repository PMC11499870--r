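# Custom makefile: the plasticity kernel is the package's hot loop and the
# R Makeconf flags for this toolchain pin -O2/-march=nocona at the end of the
# compile line, which cannot be overridden from Makevars. Flags here mirror
# Makeconf with a higher optimization level and a portable modern ISA level.
R_HOME ?= $(shell R RHOME)
include $(R_HOME)/etc/Makeconf

RCPP_INC := $(shell "$(R_HOME)/bin/Rscript" --vanilla -e 'cat(system.file("include", package = "Rcpp"))')
SPEED = -O3 -funroll-loops -march=x86-64-v2
OBJECTS = RcppExports.o kernel.o

all: podrift.so

%.o: %.cpp
	$(CXX17) $(CXX17STD) -I"$(R_INCLUDE_DIR)" -I"$(RCPP_INC)" $(CPPFLAGS) -DNDEBUG $(CXX17FLAGS) $(CXX17PICFLAGS) $(SPEED) -c $< -o $@

podrift.so: $(OBJECTS)
	$(SHLIB_CXX17LD) $(SHLIB_CXX17LDFLAGS) -o $@ $(OBJECTS) $(LIBR)

clean:
	rm -f $(OBJECTS) podrift.so
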