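>VH1a1 synthetic heavy germline
ETVKVPISFQQFYNQEALYTIALLPSDFHFWIQLYDQFNDFHTRPIPEDPYSDRMNFDAS
EFVWTPSREVPNSDIKQVTTHPQVKRQAPCLMRQNAMNKHWGQGLYHINQ
>VH1a2 synthetic heavy germline
VLEVTPNFTITSVVMSHYAVQMSRFIMSVYLWSFQAIKHTALHTQRFAIHWMHYKWNSNV
RIIQFKLMKKELIPISVEAHIDRLIYAYSCTLDYPERVHPWGQGVRYHSF
>VK1-1 synthetic kappa germline
QMTKIRELSARWNQHEEEMKRYMWKDYINTNVIFKQHDKEQDRPIMEDIDNAEYEQTNRD
QFEPMQIIWDALILSQPKKHRFQTQMHLVPCMSWPTSLNTFGQGADHYRF
>VK1-2 synthetic kappa germline
WEHYDNFNHMYYYKYLRFFTIITNMYSRVYRDHYTFFESAMKRQQYKQHQLKWETWFLPD
AQHEMNPVELWELWVHPIDNIVDDALAWPNCSFQWYRPYFFGQGDLNTWH
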