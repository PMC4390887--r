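>p1
MRIEEVPFECPDTVGGSYLCTLIFATHEPLKNYKMDSFQFCVTVFQIDEEHLVPWSTNQMSIGAPQFNSN
LLAWTLQLARMFSCTVCMGGYRCLNKICCNQRCHFLTTFDQQAKDPMYTYEYMRKTPTYDTACISDFPNA
EFRGSLH
>p2
KKDVRRTSAGMKYPFMRCGANSTMVCLEYRHTDWVKMGLKWKMMELTNGRSLCHQNWLFCDCQSELYTVV
QAEPGWHNFVHPCDARCMKLTWVNLKWRQDYLCTVWQTV
>p3
FPVKWLSCEHAQYWNWGNWHWAGKMGFQVRAKLTNAMEDGFRYCEYKQQFVLAIYFGQEKISNLQMCSQR
TWWLPGAMPLPCTRAEGLYSNSWDHDLCHWPLQMPFLWCHYMYAGLKNPVRFMIPQF
>p4
GPDPLWSTPISGKIFKLMAQEHMLILPYDHDKSMPHVHFYVHYDSIWVLYFDDSLCIAPHMMPFCRFQFT
VTVHPCNKYIYQADVCFLNDVVPRAIWIICCEWMRVIACETNSWHKWMMNTCYHTEDWATECI
>p5
DPCWKMLIAAQYMKWCCKDQCSQTYIIWRGDARNKLMGYVKNNTMIVMWAMTTIMVEQCQFAVERHQLDH
FGFWKDDKPHLTCYTNFWLSALHCLYIRQTFTTSYGDQKNKQDEDTAFENNNNRKDDK
>p6
HCPTRRYDPWCFKVAEVFDLDQLLKHGYIFWYMTHLNEYDAFFWTMAAVDFHGSPAWVFQLCSKHCRRDC
TDMFADQGWLIKDCGCSKFTNYEGCDVTFMISYAWMIKVLLDPNIGHC
>p7
FAWMCVLGENGTQAMHWFDPWVYQCAQHRGNYMLTWWLKIWHAISMLYVHIFVRCALCYTPGCWAMSWWF
IWSNRHARISMHAYFFMTTTWQVLDTLTDPQPHLEQKYWQWREDCGTLPLEDEVVCLFLPIHFTKIWPAV
AGWPWFPSQY
>p8
NYIMQCQLCLDCFRWNVVMKFKIDILLCYLSYCLQWESWMWLCFWMVNMLFPLTDQLCFNRGAPKQNVHI
NNALVTIARVQAGWMAAARVDRLNKFGMFWGISTNLIIHQRRMLWVTI
>p9
WPYDLSPVAKMFQDWMQSFLGEFNVHPLTECNPSRYNRSTTATLDTQMHLSHDGMFSPEWRICKPFNEWD
HATYLYNYCVDRNRDYGLFMANDPFMSQAAMLAYDDTWTQIGGQTYYIKQHCRHRSPTRAWISQMLRYCI
SFQHFLGTSFGFDYVWAGMN
>p10
DRRATDANCPMLGHNAWPDIRFKPREWDAFKTSTHNMNMFPFWLRCPNEMPWPHLASNDANHPKGQNVNM
KDKEQWNQNYDEPFEYAPKKPPQKCKRNVNRSNNIVMVPRHETEHFVPN
>p11
YQGCHQNIVDNWPSFFWINCAWCRAPCDAGKWDAFNGGQYDECTRDDTENIVTNCVYMGCDMGKDYCLVY
QLGETRNYNCGDNWTSQEIGRAHPFKTWGGWLRTNDCCEIFSWCFWLGPDGNEEETAVLTLLCVDYYVWV
SPQRLF
>p12
CQHSEVKPAVNTRNHCNHQTPGTFTEIHIRYYMVNWDNKHCLGYLFYTYGCDNSMYKVHPLRNKSCHQPM
DWPTYQIWLKQGQCWKFPMQGAWIPMHNKRKMRMNQKMAIMNMCDRDNKYCGFTYFMDKKMCIYDTRSAM
PNRPTSDHCTQPIVHGYLWYTRVRQR
>p13
LLYMGNGYEARLCEECNGSNCCWMHDIQAWNDAYEDCSHADEYFAGQQACSETQPWSHMKMNECYSTVED
KQQCYAGPQAGIMDQCKHAKQQ
>p14
AGDPFENEPMCVLFIHTQDCDDVFWVLSHQYCDRQLDWGIAEAPCHRYFFYAEQPEHYPRVRICFRWQVQ
VDQLIAERMKQYLYVRFVMACKYHMFNVYTVADINLNYRWHHCN
>p15
WWNQRNPICITPPGFFPFQRFKWVNHMWNAKTWVENWKSLVSLGDQKLTNEIKHFHPVMSDAQRKEHDRH
YNNKESEHCNFWCSPEYPKPRICQTYVRMMRGNLDQTMSYPYFGIKL
>p16
IACPKILPAPWPIRTEKKPWIIQQSPFPWEELFKESPCTGGMALDPTIWTTYSHPMPDHSMRYAVNFIYL
VTTAQKWYCNGIQNYWKCGVGWDWMIYWDNVIHYRRNPRLEFRLYMPKNDTHVYHDNGQERPH
>p17
YHCVMGMLNHRENFAFYYQACFQDMMFFSSYEDAEMWEVSPEVTNRWVMKYYPAAHEWVNVKEPCPQTHH
HVFCFMRENTDSKINMGVAPIACQTAAYGNMQFCVPMMNALWCM
>p18
ITIREWYTHRNFDSYYQRMMFMVCQHPKGSFKWNMLDGCDSRRNTCHISLDNTFYDKVNFQMDVSVA
>p19
HYCGFVMQEPAYIWYHLKWFRKDCTGWPWSMPKFEQMHTDVLQQQKFTIRSVSRSSIKEQLEMDTGMWLF
L
>p20
CFYCTTECYGATQSTSLDRHGNYLMDLKQCPAWWFDSHFHHHYLVEMQVRLCAMECCQCKRIAWKLHIVD
RESPQYTVARCEWKEELQKLMFKVKEMFDYFIRSVPDSDYCMLIYQHDCKKSFQDHIFEKTTFMSMTPIP
LQFSQN
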