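>p1
MRIEEVPFECVDTVGGSYLCTLIFATHEPLKNYKMDSFQFCVTVCQIDEEHLVPWSTNKMSIGAPQFNSN
LLAWTLQLARMFSTTVCMGGGRCLNKICCNYCCHFLTTFDQQATDPMYTYEYMRKTPTYDTACISDFPNA
EERGSLH
>p2
KKDVRRTSAGMKYPFMRCGANSTMVCLEYRHTDWVKMGLKMKMMELTNGRSLCHQNWLFCDCQSELYTVV
QAEPCLHNFVHPCDARCMKLTWVNLKWRQDYWCTVLQTV
>p3
FPVWWLSCEHAQYWNWGNWHKCGKMGFQLRWKLTNAMEDGFRYCEYKQPFVLAIYFGKEKISNLQMCSQR
TWWLPGAMPLPCTRAEGVYSSSWDADLCHHPLQMPDLWCHYMYAGLKNPVRRMIPQF
>p4
GPDPLWSTPISGKIFKLMAQEHMLILPYSHDKSMPHVHFEVHTDSIWVLYFDDSLCIAPHTMPFCRFQFT
VTVPPCNKYIYQADVCFLNDVVPRAIWIICCYWMRVIACETNSWKKWMTNTYYHTHDWATTRI
>p5
DPCFKMLIAAQYMKWECKDQCSVAYIIWRGDARNKLMGYWKGNTMIVMWAMTTIMVTGCQFAVERHQLDH
FGFWKDDKPWLTCYTNFWLSALHCLYIRQTFTTRYGDQKNKQDEDTAFEIMNNRTDPK
>p6
HCPTRRYDPWCFKVAEVFDLDQLLKHGYIFWYMTGLNEYDIFFWTMAAVDFHGSSAWVFQLCSKHCRRDC
TDMFPDQGWLIKDCGCSKFTNYEGCDVTVEISYAWMIKVLLDPNIFHH
>p7
FAWMCVLGENGTVAMHWFVPWVYQCAQHRGNKMLTWWLKIWHAISMLYVHIFVRCALCYTPGCWAMSWWP
IWSNRHARISMHAYFFMTTTWQVLDTLTDPQPRREQKYWQWREDCNTLPLEDEVVCLLLPIHFTKIWTAV
AGDPWFPSQY
>p8
NYIMQCQLCLDCFRWNVVMKFKIDICLCYLSYCLQWESIMWLCFWMVNMLFDLTDQLCFTRGAPKQNVHI
NNALVTIARVQAGWMAAARVMRLNKFGMFWGISTNLIIHQRRMLWVTR
>p9
WPYDLDPVAWMFQDWMQSFIGEFNVHPLTECNPSRYNRSSTATLDTWMHLSHDGMFSPEWRICKPINEWD
HGTYLYNYCVDRNRDYGLYMANDPFMSQAAMLAYDDTWTQIGGTTYYIKQHERVRSPTRAWISQMLRGCI
SFQEFLGTSFGFDYVWAGMN
>p10
DRRATDAPCPMLGHNAWPDIRRKPREWDAPKTSTHNMNMFPFWLRCPNEMRWPSLASNDANHPKGQNVNM
KDKAQQNQNYDEPFEYAPKKPPQKCKRNVNRSNNIVMVPRHETEYFVLN
>p11
YQGCHQNIVDNWPSFNWINCAWCRAPCDAGKWDAFNGGQYEWCTRDDAEAIVTNCVYMGCDMGKDYCLVY
QLGETRNYNCGDNWGSQEIGRAHPFKTWGQWLRTNCCCEIFSWCFWLGPDGNEEETAVLILLCFDYYVWV
SPQRLF
>p12
CQHSRVKPSVNTRNHCNHQTPGTCTEIHIRYYMVNWDNKHCLGYLFYTYGCDNSMYKVHPLRNKSCHQPM
DWPTGQIWLKSGQCWKIPMQGAWIPMHNKRKMRMNQKMAIMNMCDRDNKYCGFTYKMDKKMPIYDTRSAM
PNRPTSDHCTQPIVHGYLWYTRVRQR
>p13
LLYMGNGIEARLCEECNGSNCCWMHDIQAWNDAYEDCSHADEYFAGQQACSETQPWSHMKMNECYSTVED
KQQCYAGPQAIIMDQCKHAKQQ
>p14
AGDPFENEPCCVLFIHTQDCDDVFWVLSHQYCDDQLDTGIAEAPCHRYFFYAEQPEHYPRVRICFRWQVQ
VCQLIAWRMGQYLYVKFVDAAKYHMFNVYTVADINLNCRWHHYY
>p15
WWNQRNNICITPPGFFPFQTFKWVNHMWNAMTWVENWKSLVSLGDQKLTNEITHFHPVMSDAYRKEHDRH
YENKESEHCNFWCSPPYQKNRICQTYVRMMRGNLDQWMSYPYFGIKL
>p16
IACPKILPAPWPDSTELKPWIIQQSPFPWEELFKEMPCTGGMALDPTIWTTYSHPMPDHSMRYAVNFIYL
VTTAQKWYCNGIQNYWKCGVGWDWMIYWPNVICYRHNPRLEFRLYMPKNDTHVYHDNGQARPH
>p17
YHCRMYMLNHRENFAFYYQACFQDMMFFSSYEDAEMWEVSPWLTNRWVMKYYPAAHEWNNVKEPCPQTHK
HVNCFMRENTDSKINYGVAPIACQTAAYGNMQYCVPMMNALICM
>p18
ITIREWYTHRNFDSYYQRMMPNVCQHPEGSFKGNMLDGCDSRRNTCHISLDNTFYDKVRFQMDVSVA
>p19
HYCGFVHQEYAYIWYHLKWFRKDCTGWPWNNPKFDQMHTDVLQQQKFTIRSVSRSSIKEQLEMDTGMWLF
L
>p20
CFYCTTEGQGATQSTSLDRHGNYLMDLKQCPAWWFDSHFHHHYLVEMQVRLCAMECCQCKRIAWKLHWVD
RESPQYTVARCEWKEELQKLMFKVIEMFDYFIRQVPDSDYKMLIYQIDCKKSFQDHIFEKTTFMSMTPIP
LQFSQN
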