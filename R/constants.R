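# Physical and unit constants used throughout the package.
# One mmHg in pascal; fixed here so every distensibility/PWV conversion
# uses the same constant.
MMHG_TO_PA <- 133.322

# Default blood density (kg m^-3) for the Bramwell-Hill transforms.
DEFAULT_BLOOD_DENSITY <- 1059
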