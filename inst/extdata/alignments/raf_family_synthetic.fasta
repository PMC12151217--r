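>BRAF
SILIDKTSESVIRGLLVTMIVVWNKKCPAVGLFWMFLIQNVGMMGNERALSQKDGHYSDK
TGARTFKTRYQFVKIGETIMTDGADIRVPSPPRVAEDQFWVGDMALIMAKKACFQNYATD
EWFPPTWSGSEFWTNTNWDHTLSIKREDQPQFCDWAYEWEAAWSDWGLPEQGDGQLRHVD
CQISKFINKYWNLNPNVQDYPLKAMPDSTLEVNTIITQLVGITPDHHRAMCNKETTNALY
SFPWTVFFKMQGSWDGRHQHICSVFTRCCEHFADYAVSFELCMDLAAYCSWNKLDMNGCL
RWYNHDYCHMIQNKQPMPSGGESDPWYFDFQDQVPWPGNVTPCDIQTSRRSSWMTTKNAG
TCLCRGRGFEKQVWHCRITNYQENYDWAHSHAVADFIEHCHKCRTQRTYECRGILMNFQL
TWGLERITCQLVCFGNFHAIEPYRIANKRFGKWNNQWGVPQDRYHRDPHSMDFYWEDMYI
AERSGTLNRKPMEIRCWCWCVYSFAITGRMGRQGKMDWRDHIPVHMYMHTWMYIECVHWH
MCGHETMIDFFNLNGQKAVSPVPMIGPRCFEEVAVIWKSMYHFGYGLSTECNSDIWGECH
EMPTEANLAMCVATVIITWMTLAGWCDWHLATIRESLVPWMWFEYALSWVPAKYHNWDNH
IFWMLICFVKYPAHEDYNHMPWYNDSLPYNNNNMPVNWALKCCVAYNAVINDDVEDRVCW
QPERYWWIMMNDIQWITYKWKPSAHNFPGQVADSGIAKQAMFYLWN
>RAF1
------------------------------------------------------------
------------------------------------------------AKKACFQNYATD
EWFPPTWSGSEFWTNTNWDHTLSIKREDQPQFCDWAYEWEAAWSDWGLPEQGDGQLRHVD
CQISKFINKYWNLNPNVQDYPLKAMPDSTLEVNTIITQLVGITPDHHRAMCNKETTNALY
SFPWTVFFKMQGSWDGRHQHICSVFTRCCEHFADYAVSFELCMDLAAYCSWNKLDMNGCL
RWYNHDYCHMIQNKQPMPSGGESDPWYFDFQDQVPWPGNVTPCDIQTSRRSSWMTTKNAG
TCLCRGRGFEKQVWHCRITNYQENYDWAHSHAVADFIEHCHKCRTQRTYECRGILMNFQL
TWGLERITCQLVCFGNFHAIEPYRIANKRFGKWNNQWGVPQDRYHRDPHSMDFYWEDMYI
AERSGTLNRKPMEIRCWCWCVYSFAITGRMGRQGKMDWRDHIPVHMYMHTWMYIECVHWH
MCGHETMIDFFNLNGQKAVSPVPMIGPRCFEEVAVIWKSMYHFGYGLSTECNSDIWGECH
EMPTEANLAMCVATVIITWMTLAGWCDWHLATIRESLVPWMWFEYALSWVPAKYHNWDNH
IFWMLICFVKYPAHEDYNHMPWYNDSLPYNNNNMPVNWALKCCVAYNAVINDDVEDRVCW
QPERYWWIMMNDIQWITYKWKPSAHNFPGQVADSGI----------
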