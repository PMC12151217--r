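>HRAS
-------------------PMTEFNVVSGAGGVGKSSYMQKASAQAAMPQFNGIVHASCI
CVLDMIGEPAGFKPTPTYNQIFGTGQYRKPHTVWGMAFCPCNIYVSQSASRSSELREVGD
HVNFKYWLYHGRERPEFTFHLSTVGMKEIAMCNGINFDQCSTMSAKGIHIMFPRRYCCWG
DCYTEMYLMGKFVEELLEWIFFNCFIKF
>KRAS
-------------------PMTEFNVVSGAGGVGKSSYMQKASAQAAMPQFNGIVHASCI
CVLDMIGEPAGFKPTPTYNQIFGTGQYRKPHTVWGMAFCPCNIYVSQSASRSSELREVGD
HVNFKYWLYHGRERPEFTFHLSTVGMKEIAMCNGINFDQCSTMSAKGIHIMFPRRYCCWG
DCYTEMYLMGKFVEELLEWIFFNCFIKF
>NRAS
-------------------PMTEFNVVSGAGGVGKSSYMQKASAQAAMPQFNGIVHASCI
CVLDMIGEPAGFKPTPTYNQIFGTGQYRKPHTVWGMAFCPCNIYVSQSASRSSELREVGD
HVNFKYWLYHGRERPEFTFHLSTVGMKEIAMCNGINFDQCSTMSAKGIHIMFPRRYCCWG
DCYTEMYLMGKFVEELLEWIFFNCFIKF
>MRAS
---------APRIAVNQMMPMTEFNVVSGAGGVGKSSYMQKASAQAAMPQFNGIVHASCI
CVLDMIGEPAGFKPTPTYNQIFGTGQYRKPHTVWGMAFCPCNIYVSQSASRSSELREVGD
HVNFKYWLYHGRERPEFTFHLSTVGMKEIAMCNGINFDQCSTMSAKGIHIMFPRRYCCWG
DCYTEMYLMGKFVEELLEWIFFNCFIKF
>RRAS2
--------EAPRIAVNQMMPMTEFNVVSGAGGVGKSSYMQKASAQAAMPQFNGIVHASCI
CVLDMIGEPAGFKPTPTYNQIFGTGQYRKPHTVWGMAFCPCNIYVSQSASRSSELREVGD
HVNFKYWLYHGRERPEFTFHLSTVGMKEIAMCNGINFDQCSTMSAKGIHIMFPRRYCCWG
DCYTEMYLMGKFVEELLEWIFFNCFIKF
>RIT1
VCQIDDQKEAPRIAVNQMMPMTEFNVVSGAGGVGKSSYMQKASAQAAMPQFNGIVHASCI
CVLDMIGEPAGFKPTPTYNQIFGTGQYRKPHTVWGMAFCPCNIYVSQSASRSSELREVGD
HVNFKYWLYHGRERPEFTFHLSTVGMKEIAMCNGINFDQCSTMSAKGIHIMFPRRYCCWG
DCYTEMYLMGKFVEELLEWIFFNCFIKF
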