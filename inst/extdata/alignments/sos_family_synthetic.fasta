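>SOS1
FDIQIDPWDDHNTKDPVVLQAMYFRNSERHKAEGSCALIHCSEWVAGTQRRATLNEGAHM
IGVFWDFWRWSMLRKGMRVATWDPSMSLYSFDIWSGQSSPIKMYEHYEICTKLCDYKGQG
VMNAASGNSLKEMWKAEEWFRITVQCGEFAHGTNRQGYQKPMSGIAPEHQPGFHHVHNTS
KFSWDIHACENIDRAHKEISLAVGTTSICLTGLQMCRPGGKHWVGVQTIFYQIPMSLHVI
CYVPVSNEKNSVHALAMREERLKMMRDDIRCGTENPGDNFYYKKEIYHPGNCFEKNGYKC
RKELEKVMPKPITVMAYMVVPGGCFWTRCWDEAKWWYPDEFMQGIPSTPNDTGGAHIFPC
NVGVTGDINLYGNVPYSFMIGAHIPISIKEKRHSWYISMNQNPFSYARENFKLCVCNRYR
NYVATGGLEHICNNYVSHPFLHSHHDLFAHAWKKRMSSPVWMDNHMLNRPKIHIVLDCTN
WISAPLHWGADKDFSESVCWHRHLGDVYKYAPVVRHDQVRVYIHSVGMTKNVGYARQKII
SRGTCTEQQLDHAEERAAQDLGNIRQPLNYHPDNTWINLELKYYSKGFLTRGHNCLGMSH
EHFVRCSRWCTYNHMFAGLNVGHHTCVEWNCIGHNCMYSRHEEDCAADPADGTFVVEFWT
DFREPMFKNKRISGTYWNSCIACRGQSSQGSWMCFHESHRQLMVTWAWQIPTHFAIVYWT
KFHIFMPSMIMYLFAYPAMVPFIFIYGSFYLPPDHTFNLEDLGKMKMKWTYGAEWFHPQW
FCAQYGFTHSVWKAESYKVEWDQVHFFMHGFKAYSANQQPVAMCCLADQQQCFYAVTGWH
DWNCRCIDYEGFFYMTAKANFFSRNYSFLNIMGAHGVDWYTYQCRGLDDQEYDCGVKKCF
VCATFFIDHENVYWVSYYVWCHFALHHRLDICSMASITNYYIEHESYLRIWIPSVVVCWA
HHVIRVQPHENLEVVTDYNCNGSWPPLSYNCEAHYIYFIHSSGTRSMAMQQQQGHLAKHC
DLARHGLTNEWQTAGMWFWIYHPHDMHHWRLLRPWGRRTPGYVPHRWDKPIPQMYVPAQG
VRCERGMFENGITYVYAEAFPGGCEFHVAGVNVFGSGCWNWRDWESMSFHPDKPPYMHWA
DATYADESWPSVICYDGASRRYYNEIVMLGEMWIAEWPFNKDTDFLQPLEMWGWKLVVTA
WDCTQVLVLRHGSIMYWWIIKIPSNQHWQTPKVWNYVRASAKALNKYCWHHKGYGYSTAF
HDRPTMLGVHKTQMMICVVPARELWCSHIECALTSTLHSDPRNNHHCHTNKATKQYDDRQ
QSLIWYPDIWGIQ
>SOS2
FDIQIDPWDDHNTKDPVVLQAMYFRNSERHKAEGSCALIHCSEWVAGTQRRATLNEGAHM
IGVFWDFWRWSMLRKGMRVATWDPSMSLYSFDIWSGQSSPIKMYEHYEICTKLCDYKGQG
VMNAASGNSLKEMWKAEEWFRITVQCGEFAHGTNRQGYQKPMSGIAPEHQPGFHHVHNTS
KFSWDIHACENIDRAHKEISLAVGTTSICLTGLQMCRPGGKHWVGVQTIFYQIPMSLHVI
CYVPVSNEKNSVHALAMREERLKMMRDDIRCGTENPGDNFYYKKEIYHPGNCFEKNGYKC
RKELEKVMPKPITVMAYMVVPGGCFWTRCWDEAKWWYPDEFMQGIPSTPNDTGGAHIFPC
NVGVTGDINLYGNVPYSFMIGAHIPISIKEKRHSWYISMNQNPFSYARENFKLCVCNRYR
NYVATGGLEHICNNYVSHPFLHSHHDLFAHAWKKRMSSPVWMDNHMLNRPKIHIVLDCTN
WISAPLHWGADKDFSESVCWHRHLGDVYKYAPVVRHDQVRVYIHSVGMTKNVGYARQKII
SRGTCTEQQLDHAEERAAQDLGNIRQPLNYHPDNTWINLELKYYSKGFLTRGHNCLGMSH
EHFVRCSRWCTYNHMFAGLNVGHHTCVEWNCIGHNCMYSRHEEDCAADPADGTFVVEFWT
DFREPMFKNKRISGTYWNSCIACRGQSSQGSWMCFHESHRQLMVTWAWQIPTHFAIVYWT
KFHIFMPSMIMYLFAYPAMVPFIFIYGSFYLPPDHTFNLEDLGKMKMKWTYGAEWFHPQW
FCAQYGFTHSVWKAESYKVEWDQVHFFMHGFKAYSANQQPVAMCCLADQQQCFYAVTGWH
DWNCRCIDYEGFFYMTAKANFFSRNYSFLNIMGAHGVDWYTYQCRGLDDQEYDCGVKKCF
VCATFFIDHENVYWVSYYVWCHFALHHRLDICSMASITNYYIEHESYLRIWIPSVVVCWA
HHVIRVQPHENLEVVTDYNCNGSWPPLSYNCEAHYIYFIHSSGTRSMAMQQQQGHLAKHC
DLARHGLTNEWQTAGMWFWIYHPHDMHHWRLLRPWGRRTPGYVPHRWDKPIPQMYVPAQG
VRCERGMFENGITYVYAEAFPGGCEFHVAGVNVFGSGCWNWRDWESMSFHPDKPPYMHWA
DATYADESWPSVICYDGASRRYYNEIVMLGEMWIAEWPFNKDTDFLQPLEMWGWKLVVTA
WDCTQVLVLRHGSIMYWWIIKIPSNQHWQTPKVWNYVRASAKALNKYCWHHKGYGYSTAF
HDRPTMLGVHKTQMMICVVPARELWCSHIECALTSTLHSDPRNNHHCHTNKATKQYDDRQ
QSLIWYPDIWGI-
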