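>MAP2K2
YHRAGHIANSFYHAMEAGLGWWWFIEDRCVPEFHWHLISINAMPHFFWCYQIHDLIKIFW
NAGDIMNRAELHPSVAIGNLKHDGPGVYFSQFYNYSHCIGSWDATADHKGWDMVFEYSKD
LRYVTCRSEIHKVAEMWVKACDEQDGYADPVVVGHPNCDCEPDWCFMFVTVDIWDCFVCE
PVCDTDVMSWYWKRQMQVITNQSSAHNYCMGSWVRRTSQHMDIYEQYHNFLYWMHNLNHT
KSIQGFSAHAGTRAWVISSHFSEWENKHYRPDESPVTITNICFCMDNVVYQCKPENKIYG
TDVFNCGNAIHVAEKTLYTCNEVRECLHYHTVHWNQSEYSYVEMEQHHVLCMVYGAWTAK
IIAITMINLLCCHMPTRSGGPANLFKEWYVGPAQKNHTGC
>MAP2K1
----GHIANSFYHAMEAGLGWWWFIEDRCVPEFHWHLISINAMPHFFWCYQIHDLIKIFW
NAGDIMNRAELHPSVAIGNLKHDGPGVYFSQFYNYSHCIGSWDATADHKGWDMVFEYSKD
LRYVTCRSEIHKVAEMWVKACDEQDGYADPVVVGHPNCDCEPDWCFMFVTVDIWDCFVCE
PVCDTDVMSWYWKRQMQVITNQSSAHNYCMGSWVRRTSQHMDIYEQYHNFLYWMHNLNHT
KSIQGFSAHAGTRAWVISSHFSEWENKHYRPDESPVTITNICFCMDNVVYQCKPENKIYG
TDVFNCGNAIHVAEKTLYTCNEVRECLHYHTVHWNQSEYSYVEMEQHHVLCMVYGAWTAK
IIAITMINLLCCHMPTRSGGPANLFKEWYVGPAQKNH---
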